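#' Initial velocity from an A340 slope
#'
#' Converts an NADH-oxidation absorbance slope at 340 nm into a velocity
#' using \eqn{\varepsilon_{340} = 6.22} mM^-1 cm^-1:
#' \eqn{v = |slope| / (6.22\,\ell) \times 1000 / 60} µM s^-1.
#'
#' @param slope Absorbance change per minute at 340 nm.
#' @param path Optical path, cm.
#' @return Velocity, µM s^-1.
#' @examples
#' rate_from_a340(0.373)  # ~1.0 uM/s
#' @export
rate_from_a340 <- function(slope, path = 1) {
  if (path <= 0) stop("`path` must be > 0")
  abs(slope) / (6.22 * path) * 1000 / 60
}

#' Fit the Michaelis-Menten model
#'
#' Unweighted nonlinear least squares of
#' \eqn{v = k_{cat} E_0 S / (K_m + S)}; an optional `weight_inverse_v2`
#' flag applies 1/v^2 weights. The specificity constant is reported in
#' mM^-1 s^-1 with a first-order (delta-method) standard error.
#'
#' @param data A [rate_dataset()].
#' @param weight_inverse_v2 Use 1/v^2 weighting (default `FALSE`).
#' @return An `mm_fit` with `km` (µM), `kcat` (s^-1), their SEs,
#'   `specificity` (mM^-1 s^-1) with SE, `converged`, and a `km_flag` set
#'   when K_m falls outside 100x the substrate range.
#' @export
fit_mm <- function(data, weight_inverse_v2 = FALSE) {
  if (!inherits(data, "rate_dataset")) stop("`data` must be a rate_dataset")
  e0 <- attr(data, "enzyme_total")
  s <- data$S_uM; v <- data$v_uM_per_s
  vmax0 <- max(v)
  km0 <- s[which.min(abs(v - vmax0 / 2))]
  if (km0 <= 0) km0 <- stats::median(s)
  w <- if (weight_inverse_v2) 1 / pmax(v, 1e-12)^2 else rep(1, length(v))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ kcat * e0 * s / (km + s),
                      data = data.frame(s = s, v = v, e0 = e0),
                      start = list(kcat = vmax0 / e0, km = km0),
                      weights = w,
                      lower = c(kcat = 0, km = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(converged = FALSE,
                          message = conditionMessage(fit)),
                     class = "mm_fit"))
  est <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA, 2, 2))
  se <- sqrt(diag(vc))
  km <- est[["km"]]; kcat <- est[["kcat"]]
  spec <- specificity(km, kcat)
  # delta method on kcat/Km with the fit covariance
  grad <- c(kcat = 1000 / km, km = -1000 * kcat / km^2)
  vc2 <- vc[c("kcat", "km"), c("kcat", "km")]
  spec_se <- sqrt(drop(t(grad) %*% vc2 %*% grad))
  km_flag <- km > 100 * max(data$S_uM) || km < min(data$S_uM) / 100
  structure(list(km = km, km_se = unname(se["km"]),
                 kcat = kcat, kcat_se = unname(se["kcat"]),
                 specificity = spec, specificity_se = spec_se,
                 converged = TRUE, km_flag = km_flag, fit = fit),
            class = "mm_fit")
}

#' @export
print.mm_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<mm_fit> NOT converged:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<mm_fit> K_m = %.3g +/- %.2g uM, k_cat = %.4g +/- %.2g s^-1, k_cat/K_m = %.4g +/- %.2g mM^-1 s^-1\n",
    x$km, x$km_se, x$kcat, x$kcat_se, x$specificity, x$specificity_se))
  if (x$km_flag) cat("  WARNING: K_m far outside the substrate range\n")
  invisible(x)
}

#' Specificity constant
#'
#' \eqn{k_{cat}/K_m} with K_m in µM, reported in mM^-1 s^-1.
#'
#' @param km Michaelis constant, µM.
#' @param kcat Catalytic constant, s^-1.
#' @return Specificity constant, mM^-1 s^-1.
#' @examples
#' specificity(22, 258)  # 11727
#' @export
specificity <- function(km, kcat) {
  if (any(km <= 0)) stop("`km` must be > 0")
  kcat / (km / 1000)
}

#' Fit the bi-bi ping-pong rate law
#'
#' Global nonlinear least squares of
#' \eqn{v = k_{cat} E_0 A B / (K_a B + K_b A + A B)} across all
#' (A, B) pairs. Double-reciprocal plots are diagnostic only: the
#' `parallelism_stat` is the coefficient of variation of the per-B-level
#' slopes of 1/v against 1/A, which is ~0 under a ping-pong mechanism
#' (those slopes equal \eqn{K_a/V_{max}} independent of B) and grows when a
#' ternary-complex term is present.
#'
#' @param data A [pingpong_dataset()].
#' @param parallel_tol `parallelism_stat` above which a mechanism warning is
#'   raised (default 0.15).
#' @return A `pingpong_fit` with `kcat`, `ka`, `kb`, their SEs,
#'   `parallelism_stat` and `converged`.
#' @export
fit_pingpong <- function(data, parallel_tol = 0.15) {
  if (!inherits(data, "pingpong_dataset"))
    stop("`data` must be a pingpong_dataset")
  if (length(unique(data$B_uM)) < 3L || length(unique(data$A_uM)) < 4L)
    stop("need >= 3 B levels and >= 4 A levels")
  e0 <- attr(data, "enzyme_total")
  df <- data.frame(a = data$A_uM, b = data$B_uM, v = data$v_uM_per_s, e0 = e0)
  # reciprocal-slope diagnostic per B level
  slopes <- vapply(split(df, df$b), function(d) {
    if (nrow(d) < 2L) return(NA_real_)
    unname(stats::coef(stats::lm(I(1 / v) ~ I(1 / a), data = d))[2])
  }, numeric(1))
  slopes <- slopes[is.finite(slopes)]
  parallelism <- stats::sd(slopes) / abs(mean(slopes))
  fit <- tryCatch(
    minpack.lm::nlsLM(v ~ kcat * e0 * a * b / (ka * b + kb * a + a * b),
                      data = df,
                      start = list(kcat = max(df$v) / e0,
                                   ka = stats::median(df$a),
                                   kb = stats::median(df$b)),
                      lower = c(kcat = 1e-12, ka = 1e-12, kb = 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    return(structure(list(converged = FALSE, message = conditionMessage(fit),
                          parallelism_stat = parallelism),
                     class = "pingpong_fit"))
  est <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))),
                 error = function(e) rep(NA_real_, 3))
  mech_warning <- is.finite(parallelism) && parallelism > parallel_tol
  if (mech_warning)
    warning(sprintf(
      "double-reciprocal slopes vary by %.0f%% across B levels: ping-pong mechanism suspect",
      100 * parallelism))
  structure(list(kcat = est[["kcat"]], kcat_se = unname(se["kcat"]),
                 ka = est[["ka"]], ka_se = unname(se["ka"]),
                 kb = est[["kb"]], kb_se = unname(se["kb"]),
                 parallelism_stat = parallelism,
                 mechanism_warning = mech_warning,
                 converged = TRUE, fit = fit),
            class = "pingpong_fit")
}

#' @export
print.pingpong_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<pingpong_fit> NOT converged:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<pingpong_fit> k_cat = %.3g +/- %.2g s^-1, K_a = %.3g +/- %.2g uM, K_b = %.3g +/- %.2g uM\n",
    x$kcat, x$kcat_se, x$ka, x$ka_se, x$kb, x$kb_se))
  cat(sprintf("  parallelism stat (CV of 1/v~1/A slopes) = %.3g%s\n",
              x$parallelism_stat,
              if (isTRUE(x$mechanism_warning)) "  ** non-parallel **" else ""))
  invisible(x)
}

#' Catalytic constant from a specific activity
#'
#' \eqn{k_{cat} = V_{max}\,M_{subunit} / 60000} converts a specific
#' activity in µmol min^-1 mg^-1 into a per-active-site turnover number in
#' s^-1 (one catalytic site per subunit).
#'
#' @param sa Specific activity, µmol min^-1 mg^-1.
#' @param subunit_mass Subunit molecular mass, Da.
#' @return k_cat, s^-1.
#' @examples
#' kcat_from_specific_activity(1111, 21412)  # 396.5, displayed 397
#' @export
kcat_from_specific_activity <- function(sa, subunit_mass) {
  if (sa < 0 || subunit_mass <= 0)
    stop("`sa` must be >= 0 and `subunit_mass` > 0")
  sa * subunit_mass / 60000
}

#' Kinetic isotope effect
#'
#' Ratio of the rate with the light isotope to the rate with the heavy
#' isotope, with first-order SE propagation when standard errors are
#' supplied.
#'
#' @param rate_h Rate with the light isotope, s^-1.
#' @param rate_d Rate with the heavy isotope, s^-1.
#' @param se_h,se_d Optional standard errors.
#' @return The ratio; when SEs are given, a list with `value` and `se`.
#' @examples
#' kie(258, 47.3)  # ~5.45
#' @export
kie <- function(rate_h, rate_d, se_h = NULL, se_d = NULL) {
  if (rate_d <= 0) stop("heavy-isotope rate must be > 0")
  ratio <- rate_h / rate_d
  if (is.null(se_h) && is.null(se_d)) return(ratio)
  se_h <- se_h %||% 0; se_d <- se_d %||% 0
  se <- ratio * sqrt((se_h / rate_h)^2 + (se_d / rate_d)^2)
  list(value = ratio, se = se)
}

#' Ratio of two catalytic constants
#'
#' Used e.g. to compare flavin-reductase and quinone-reductase activities of
#' the same enzyme.
#'
#' @param kcat_a,kcat_b Catalytic constants, s^-1.
#' @param se_a,se_b Optional standard errors.
#' @return The ratio; when SEs are given, a list with `value` and `se`.
#' @export
activity_ratio <- function(kcat_a, kcat_b, se_a = NULL, se_b = NULL) {
  if (kcat_b <= 0) stop("`kcat_b` must be > 0")
  ratio <- kcat_a / kcat_b
  if (is.null(se_a) && is.null(se_b)) return(ratio)
  se_a <- se_a %||% 0; se_b <- se_b %||% 0
  list(value = ratio,
       se = ratio * sqrt((se_a / kcat_a)^2 + (se_b / kcat_b)^2))
}
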