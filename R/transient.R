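#' Fit a single-exponential decay to a stopped-flow trace
#'
#' Least squares of \eqn{A(t) = \mathrm{offset} + \mathrm{amplitude}\,
#' e^{-k_{obs} t}}. Starting values come from a log-linear transform of the
#' baseline-subtracted signal (the tail mean estimates the offset). The fit
#' is flagged as under-sampled when \eqn{k_{obs} t_{max} < 1} and as
#' flat/unidentifiable when the trace carries no decay amplitude. A lag-one
#' residual autocorrelation statistic warns when a second kinetic phase is
#' present.
#'
#' @param trace A [stopped_flow_trace()].
#' @param dead_time Optional dead-time shift, s, added to the time base
#'   before fitting (traces are normally pre-trimmed).
#' @return An `exp_fit` with `kobs`, `amplitude`, `offset` (with SEs),
#'   `converged`, `undersampled`, `residual_autocorr` and `biphasic_warning`.
#' @export
fit_exponential <- function(trace, dead_time = 0) {
  if (!inherits(trace, "stopped_flow_trace"))
    stop("`trace` must be a stopped_flow_trace")
  t <- trace$t_s + dead_time
  a <- trace$A450
  off0 <- mean(utils::tail(a, max(3L, length(a) %/% 10)))
  amp0 <- a[1] - off0
  rng <- diff(range(a))
  if (abs(amp0) < 1e-6 * max(abs(a), 1) && rng < 1e-6 * max(abs(a), 1))
    return(structure(list(kobs = NA_real_, amplitude = 0, offset = mean(a),
                          converged = FALSE, flat = TRUE,
                          message = "flat trace: k_obs unidentifiable"),
                     class = "exp_fit"))
  z <- amp0 * exp(-1) # crude guess: time to 1/e of the amplitude
  t_e <- t[which.min(abs((a - off0) - z))]
  k0 <- if (t_e > 0) 1 / t_e else 1 / stats::median(t[t > 0])
  pos <- (a - off0) / amp0 > 0.05
  if (sum(pos) >= 3) {
    lf <- stats::lm(log((a[pos] - off0) / amp0) ~ t[pos])
    k_lin <- -unname(stats::coef(lf)[2])
    if (is.finite(k_lin) && k_lin > 0) k0 <- k_lin
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(a ~ off + amp * exp(-k * t),
                      data = data.frame(t = t, a = a),
                      start = list(off = off0, amp = amp0, k = k0),
                      lower = c(off = -Inf, amp = -Inf, k = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(kobs = k0, converged = FALSE, flat = FALSE,
                          message = conditionMessage(fit)),
                     class = "exp_fit"))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 3))
  r <- stats::resid(fit)
  ac <- if (length(r) > 2 && stats::sd(r) > 0)
    suppressWarnings(stats::cor(r[-1], r[-length(r)])) else NA_real_
  structure(list(kobs = est[["k"]], kobs_se = unname(se["k"]),
                 amplitude = est[["amp"]], amplitude_se = unname(se["amp"]),
                 offset = est[["off"]], offset_se = unname(se["off"]),
                 converged = TRUE, flat = FALSE,
                 undersampled = est[["k"]] * max(t) < 1,
                 residual_autocorr = ac,
                 biphasic_warning = is.finite(ac) && ac > 0.5,
                 fit = fit),
            class = "exp_fit")
}

#' @export
print.exp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<exp_fit> NOT converged:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<exp_fit> k_obs = %.4g +/- %.2g s^-1, amplitude %.3g, offset %.3g\n",
    x$kobs, x$kobs_se, x$amplitude, x$offset))
  if (isTRUE(x$undersampled)) cat("  WARNING: k_obs * t_max < 1 (under-sampled)\n")
  if (isTRUE(x$biphasic_warning))
    cat("  WARNING: structured residuals; a second phase may be present\n")
  invisible(x)
}

#' Fit the hyperbolic k_obs-concentration dependence
#'
#' Least squares of \eqn{k_{obs} = k_{max} S / (k_{half} + S)}, the
#' saturation behaviour of the reductive half-reaction: \eqn{k_{max}} is the
#' limiting electron-transfer rate constant and \eqn{k_{half}} the apparent
#' substrate affinity.
#'
#' @param points Data frame with columns `nadh_uM` and `kobs` (or a
#'   two-column matrix in that order).
#' @return A `hyperbola_fit` with `k_max`, `k_half`, SEs, `converged` and a
#'   `k_half_flag` set when all concentrations sit far above `k_half`
#'   (half-saturation then unidentifiable).
#' @export
fit_kobs_hyperbola <- function(points) {
  points <- as.data.frame(points)
  if (!all(c("nadh_uM", "kobs") %in% names(points)))
    names(points)[1:2] <- c("nadh_uM", "kobs")
  if (nrow(points) < 4L) stop("need at least 4 concentrations")
  s <- points$nadh_uM; k <- points$kobs
  kmax0 <- max(k)
  khalf0 <- s[which.min(abs(k - kmax0 / 2))]
  if (khalf0 <= 0) khalf0 <- stats::median(s)
  # direct Levenberg-Marquardt on the residuals: saturated designs make the
  # start-point gradient nearly collinear, which nls-style front ends reject
  fit <- tryCatch(
    minpack.lm::nls.lm(par = c(kmax = kmax0, khalf = khalf0),
                       lower = c(0, 1e-9),
                       fn = function(p) k - p[1] * s / (p[2] + s),
                       control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) e)
  if (inherits(fit, "error") || fit$info %in% c(0, 9))
    return(structure(list(converged = FALSE,
                          message = if (inherits(fit, "error"))
                            conditionMessage(fit) else fit$message),
                     class = "hyperbola_fit"))
  est <- fit$par
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) stats::setNames(rep(NA_real_, 2),
                                                     names(est)))
  flag <- min(s) > 10 * est[["khalf"]]
  structure(list(k_max = est[["kmax"]], k_max_se = unname(se["kmax"]),
                 k_half = est[["khalf"]], k_half_se = unname(se["khalf"]),
                 k_half_flag = flag, converged = TRUE, fit = fit),
            class = "hyperbola_fit")
}

#' @export
print.hyperbola_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<hyperbola_fit> NOT converged:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<hyperbola_fit> k_max = %.4g +/- %.2g s^-1, half-saturation %.3g +/- %.2g uM\n",
    x$k_max, x$k_max_se, x$k_half, x$k_half_se))
  if (isTRUE(x$k_half_flag))
    cat("  WARNING: all concentrations >> k_half; half-saturation unreliable\n")
  invisible(x)
}

#' Kinetic solvent isotope effect
#'
#' \eqn{k_{obs}(\mathrm{H_2O}) / k_{obs}(\mathrm{D_2O})} with delta-method
#' SE propagation when standard errors are supplied.
#'
#' @param k_h2o,k_d2o Observed rate constants in the two solvents, s^-1.
#' @param se_h2o,se_d2o Optional standard errors.
#' @return The ratio; with SEs, a list with `value` and `se`.
#' @examples
#' solvent_kie(147, 77.4)  # ~1.9
#' @export
solvent_kie <- function(k_h2o, k_d2o, se_h2o = NULL, se_d2o = NULL) {
  if (k_d2o <= 0) stop("`k_d2o` must be > 0")
  kie(k_h2o, k_d2o, se_h2o, se_d2o)
}
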