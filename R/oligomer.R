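#' Calibrate a size-exclusion column
#'
#' Ordinary least squares of log10(mass) on elution volume over the marker
#' proteins, the standard linear SEC calibration.
#'
#' @param markers A [sec_marker_table()].
#' @return A `sec_calibration` with `intercept`, `slope` (per mL), their
#'   SEs, `r_squared` and the marker range.
#' @examples
#' sec_calibrate(sec_markers_superose12())
#' @export
sec_calibrate <- function(markers) {
  if (!inherits(markers, "sec_marker_table"))
    stop("`markers` must be a sec_marker_table")
  fit <- stats::lm(log10(mass_kda) ~ elution_ml, data = markers)
  cf <- suppressWarnings(summary(fit))$coefficients
  structure(list(intercept = cf[1, 1], slope = cf[2, 1],
                 intercept_se = cf[1, 2], slope_se = cf[2, 2],
                 r_squared = suppressWarnings(summary(fit))$r.squared,
                 ve_range = range(markers$elution_ml),
                 lm = fit),
            class = "sec_calibration")
}

#' @export
print.sec_calibration <- function(x, ...) {
  cat(sprintf(
    "<sec_calibration> log10(kDa) = %.3f %+.4f x Ve (R^2 = %.4f, Ve %g-%g mL)\n",
    x$intercept, x$slope, x$r_squared, x$ve_range[1], x$ve_range[2]))
  invisible(x)
}

#' Apparent native mass from an elution volume
#'
#' @param calibration A [sec_calibrate()] result.
#' @param elution_ml Query elution volume, mL.
#' @return A list with `mass_da`, `mass_kda` and `extrapolated` (`TRUE` when
#'   the query lies outside the marker range).
#' @export
sec_apparent_mass <- function(calibration, elution_ml) {
  stopifnot(inherits(calibration, "sec_calibration"))
  mass_kda <- 10^(calibration$intercept + calibration$slope * elution_ml)
  list(mass_da = mass_kda * 1000, mass_kda = mass_kda,
       extrapolated = elution_ml < calibration$ve_range[1] |
         elution_ml > calibration$ve_range[2])
}

#' Subunits per native particle
#'
#' @param apparent_mass Apparent native mass, Da.
#' @param monomer_mass Subunit mass, Da.
#' @return Apparent mass over monomer mass, rounded to two decimals.
#' @examples
#' subunit_count(40022, 21288)  # 1.88
#' @export
subunit_count <- function(apparent_mass, monomer_mass) {
  if (apparent_mass <= 0 || monomer_mass <= 0) stop("masses must be > 0")
  round(apparent_mass / monomer_mass, 2)
}

# Exact non-negative weighted least squares by active-subset enumeration:
# minimizes || (y - X v) / sigma ||^2 over v >= 0. Exact for small K.
.nnls_enum <- function(x, y, sigma) {
  k <- ncol(x)
  xw <- x / sigma; yw <- y / sigma
  best <- list(rss = Inf, v = rep(0, k), subset = integer(0))
  for (mask in seq_len(2^k - 1L)) {
    idx <- which(bitwAnd(mask, 2^(seq_len(k) - 1L)) > 0)
    fit <- tryCatch(stats::lm.fit(xw[, idx, drop = FALSE], yw),
                    error = function(e) NULL)
    if (is.null(fit) || anyNA(fit$coefficients)) next
    if (any(fit$coefficients < 0)) next
    rss <- sum(fit$residuals^2)
    if (rss < best$rss) {
      v <- rep(0, k); v[idx] <- fit$coefficients
      best <- list(rss = rss, v = v, subset = idx)
    }
  }
  # all-zero solution as fallback
  rss0 <- sum(yw^2)
  if (rss0 < best$rss) best <- list(rss = rss0, v = rep(0, k),
                                    subset = integer(0))
  best
}

#' Decompose a scattering curve over component form factors
#'
#' Finds the scale c and non-negative weights w (summing to 1) minimizing
#' the reduced chi-square
#' \deqn{\chi^2 = \frac{1}{N - K} \sum_j \left(\frac{I_{exp}(q_j) -
#'   c \sum_i w_i I_i(q_j)}{\sigma_j}\right)^2,}
#' the OLIGOMER-style volume-fraction fit. The problem is linear in
#' \eqn{v_i = c\,w_i \ge 0} and is solved exactly by non-negative weighted
#' least squares; weight standard errors come from the linear-fit
#' covariance via the delta method.
#'
#' @param curve A [scattering_curve()].
#' @param components A [form_factor_set()]; if its q grid differs from the
#'   curve's, components are linearly interpolated and the result flagged.
#' @return A `mixture_fit` with `weights` (named, summing to 1),
#'   `weights_se`, `scale`, `chi` (reduced chi-square), `interpolated` and
#'   an ill-conditioning flag.
#' @export
fit_mixture <- function(curve, components) {
  stopifnot(inherits(curve, "scattering_curve"),
            inherits(components, "form_factor_set"))
  interpolated <- FALSE
  comp <- components$intensities
  if (length(components$q) != nrow(curve) ||
      any(abs(components$q - curve$q) > 1e-12)) {
    if (min(curve$q) < min(components$q) || max(curve$q) > max(components$q))
      stop("curve q range extends beyond the component form factors")
    comp <- apply(components$intensities, 2, function(col)
      stats::approx(components$q, col, xout = curve$q)$y)
    interpolated <- TRUE
  }
  k <- ncol(comp)
  n <- nrow(curve)
  if (n <= k) stop("more components than usable q points")
  sol <- .nnls_enum(comp, curve$I, curve$sigma)
  v <- sol$v
  chi <- sol$rss / (n - k)
  scale <- sum(v)
  if (scale <= 0)
    return(structure(list(weights = stats::setNames(rep(NA_real_, k),
                                                    colnames(comp)),
                          weights_se = rep(NA_real_, k), scale = 0,
                          chi = chi, converged = FALSE,
                          message = "curve has no positive projection"),
                     class = "mixture_fit"))
  w <- v / scale
  # covariance of the active coefficients, delta method to w = v / sum(v)
  w_se <- rep(NA_real_, k)
  ill_conditioned <- FALSE
  if (length(sol$subset) > 0) {
    xw <- comp[, sol$subset, drop = FALSE] / curve$sigma
    xtx <- crossprod(xw)
    cond <- kappa(xtx, exact = TRUE)
    ill_conditioned <- !is.finite(cond) || cond > 1e10
    cov_v <- tryCatch(chi * solve(xtx), error = function(e) NULL)
    if (!is.null(cov_v)) {
      jac <- matrix(0, length(sol$subset), length(sol$subset))
      va <- v[sol$subset]
      for (i in seq_along(va)) for (j in seq_along(va))
        jac[i, j] <- (as.numeric(i == j) * scale - va[i]) / scale^2
      cov_w <- jac %*% cov_v %*% t(jac)
      w_se[sol$subset] <- sqrt(pmax(diag(cov_w), 0))
    }
  }
  structure(list(weights = stats::setNames(w, colnames(comp)),
                 weights_se = stats::setNames(w_se, colnames(comp)),
                 scale = scale, chi = chi,
                 interpolated = interpolated,
                 ill_conditioned = ill_conditioned,
                 converged = TRUE),
            class = "mixture_fit")
}

#' @export
print.mixture_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<mixture_fit> failed:", x$message, "\n")
    return(invisible(x))
  }
  cat("<mixture_fit> volume fractions:\n")
  for (nm in names(x$weights))
    cat(sprintf("  %-12s %5.1f%%  (se %.3g)\n", nm, 100 * x$weights[nm],
                x$weights_se[nm]))
  cat(sprintf("  scale %.4g, reduced chi^2 = %.3g%s\n", x$scale, x$chi,
              if (isTRUE(x$ill_conditioned)) "  ** ill-conditioned **" else ""))
  invisible(x)
}
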