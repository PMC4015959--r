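#' Deconvolve a two-couple absorbance series into oxidized fractions
#'
#' Per time point, solves the linear system
#' \eqn{A(\lambda) = \ell \sum_s \varepsilon_{s\lambda} c_s} for the
#' oxidized concentrations of the enzyme flavin and the dye, using the two
#' closure constraints \eqn{[ox] + [red] = \mathrm{total}} to eliminate the
#' reduced species. Fractions outside [0, 1] (possible under noise) are
#' clipped and flagged.
#'
#' @param series An [absorbance_series()].
#' @param eps An [extinction_matrix()] on the same wavelengths.
#' @param max_condition Condition-number limit above which the 2x2 system is
#'   rejected as singular.
#'
#' @return A data frame with columns `t_min`, `f_ox_enzyme`, `f_ox_dye`,
#'   `clipped`; attribute `condition` carries the condition number of the
#'   deconvolution matrix.
#' @export
deconvolve <- function(series, eps, max_condition = 1e8) {
  stopifnot(inherits(series, "absorbance_series"),
            inherits(eps, "extinction_matrix"))
  if (!isTRUE(all.equal(series$wavelengths, eps$wavelengths)))
    stop("wavelengths of the series and the extinction matrix differ")
  e <- eps$eps
  # effective 2x2 system in (flavin_ox, dye_ox) after closure elimination
  m <- rbind(e["flavin_ox", ] - e["flavin_red", ],
             e["dye_ox", ] - e["dye_red", ])
  kappa <- kappa(m, exact = TRUE)
  if (!is.finite(kappa) || kappa > max_condition)
    stop(sprintf(
      "singular extinction configuration (condition number %.3g)", kappa))
  ell <- series$path_length
  # background from the fully reduced species at the known totals (mM units)
  bg <- (series$f_tot * e["flavin_red", ] + series$d_tot * e["dye_red", ]) / 1000
  sol <- apply(series$absorbance, 1, function(a) {
    b <- a / ell - bg
    qr.solve(t(m), b) * 1000  # uM (least squares when > 2 wavelengths)
  })
  f_ox <- sol[1, ] / series$f_tot
  d_ox <- sol[2, ] / series$d_tot
  clipped <- f_ox < 0 | f_ox > 1 | d_ox < 0 | d_ox > 1
  structure(data.frame(t_min = series$times,
                       f_ox_enzyme = pmin(pmax(f_ox, 0), 1),
                       f_ox_dye = pmin(pmax(d_ox, 0), 1),
                       clipped = clipped),
            condition = kappa,
            class = c("redox_fractions", "data.frame"))
}

#' Reference redox dye library
#'
#' Midpoint potentials (pH 7) of the indicator dyes used for dye-coupled
#' potentiometry, user-extensible via `extra`.
#'
#' @param extra Optional named list of `list(e_mv =, n =)` entries that
#'   extend or override the defaults.
#' @return A data frame with columns `dye`, `e_mv`, `n`.
#' @examples
#' dye_library()
#' @export
dye_library <- function(extra = NULL) {
  tbl <- data.frame(
    dye = c("indigo_carmine", "phenosafranin", "anthraquinone_2_sulfonate"),
    e_mv = c(-125, -252, -225),
    n = c(2L, 2L, 2L))
  if (!is.null(extra)) {
    for (nm in names(extra)) {
      row <- data.frame(dye = nm, e_mv = extra[[nm]]$e_mv,
                        n = as.integer(extra[[nm]]$n %||% 2L))
      tbl <- rbind(tbl[tbl$dye != nm, ], row)
    }
  }
  tbl
}

#' Look up a reference dye
#'
#' @param name Dye name as in [dye_library()].
#' @param library Dye table, defaults to [dye_library()].
#' @return A list with `e_mv` and `n`.
#' @export
dye_lookup <- function(name, library = dye_library()) {
  hit <- library[library$dye == name, ]
  if (nrow(hit) != 1L)
    stop(sprintf("unknown dye '%s'; known: %s", name,
                 paste(library$dye, collapse = ", ")))
  list(e_mv = hit$e_mv, n = hit$n)
}

#' Midpoint potential from the Nernst-plot intercept
#'
#' Applies the operational relation
#' \deqn{E_m = E_{dye} + \frac{\nu}{n_F}\,\mathrm{intercept}}
#' used to convert the vertical-axis intercept of the equilibration plot
#' into the enzyme midpoint potential, with \eqn{\nu} the Nernst slope in
#' mV per decade. With the package's log10(red/ox) plot orientation this
#' relation is exact (see [equilibration_fit()]).
#'
#' @param e_dye Dye midpoint potential, mV.
#' @param intercept Vertical-axis intercept of the equilibration plot.
#' @param n_f Electrons of the enzyme couple (1 or 2).
#' @param nernst_slope_mv Nernst slope, mV per decade (default 59).
#' @return Midpoint potential, mV.
#' @examples
#' potential_from_intercept(-125, -0.45, 2)  # -138.275 mV
#' @export
potential_from_intercept <- function(e_dye, intercept, n_f,
                                     nernst_slope_mv = 59) {
  if (!n_f %in% c(1, 2)) stop("`n_f` must be 1 or 2")
  e_dye + (nernst_slope_mv / n_f) * intercept
}

#' Fit the two-couple Nernst equilibration plot
#'
#' Regresses the enzyme log-ratio on the dye log-ratio across the
#' equilibration time course. The slope estimates \eqn{n_F/n_D} and the
#' intercept, through [potential_from_intercept()], the enzyme midpoint
#' potential. Axes carry log10(red/ox); this orientation leaves the slope
#' equal to \eqn{n_F/n_D} and makes the standard intercept arithmetic
#' \eqn{E_m = E_{dye} + (\nu/n_F)\,b} hold exactly (with log10(ox/red) axes
#' the intercept's sign is reversed).
#'
#' Points with either fraction outside the window are excluded: the
#' log-ratio variance explodes as a couple approaches fully oxidized or
#' fully reduced.
#'
#' @param fractions Output of [deconvolve()] (columns `f_ox_enzyme`,
#'   `f_ox_dye`), or any data frame with those columns.
#' @param e_dye Dye midpoint potential, mV (or a dye name known to
#'   [dye_library()]).
#' @param n_f,n_d Electrons of the enzyme and dye couples.
#' @param window Inclusion window on both oxidized fractions
#'   (default `c(0.1, 0.9)`).
#' @param nernst_slope_mv Nernst slope, mV per decade.
#'
#' @return A `nernst_fit` with slope, intercept (each with SE), `e_m` (mV),
#'   `n_used` points, the regression table and a `slope_warning` flag set
#'   when the slope deviates more than 25% from \eqn{n_F/n_D}.
#' @export
equilibration_fit <- function(fractions, e_dye, n_f = 2L, n_d = 2L,
                              window = c(0.1, 0.9), nernst_slope_mv = 59) {
  if (is.character(e_dye)) {
    dye <- dye_lookup(e_dye)
    if (missing(n_d)) n_d <- dye$n
    e_dye <- dye$e_mv
  }
  fo <- fractions$f_ox_enzyme
  fd <- fractions$f_ox_dye
  use <- fo > window[1] & fo < window[2] & fd > window[1] & fd < window[2]
  if (sum(use) < 3L)
    stop("fewer than 3 time points with both fractions inside the window")
  # log10(red/ox) orientation
  y <- log10((1 - fo[use]) / fo[use])
  x <- log10((1 - fd[use]) / fd[use])
  fit <- stats::lm(y ~ x)
  cf <- suppressWarnings(summary(fit))$coefficients  # noiseless fits are legitimately perfect
  slope <- cf["x", "Estimate"]
  intercept <- cf["(Intercept)", "Estimate"]
  e_m <- potential_from_intercept(e_dye, intercept, n_f, nernst_slope_mv)
  slope_warning <- abs(slope - n_f / n_d) > 0.25 * (n_f / n_d)
  if (slope_warning)
    warning(sprintf(
      "slope %.3f deviates > 25%% from n_F/n_D = %.2f: equilibrium suspect",
      slope, n_f / n_d))
  structure(list(slope = slope, slope_se = cf["x", "Std. Error"],
                 intercept = intercept,
                 intercept_se = cf["(Intercept)", "Std. Error"],
                 e_dye = e_dye, n_f = n_f, n_d = n_d, e_m = e_m,
                 nernst_slope_mv = nernst_slope_mv,
                 n_used = sum(use), slope_warning = slope_warning,
                 regression = data.frame(log_rd_ox_dye = x,
                                         log_rd_ox_enzyme = y),
                 lm = fit),
            class = "nernst_fit")
}

#' @export
print.nernst_fit <- function(x, ...) {
  cat(sprintf(
    "<nernst_fit> slope %.3f +/- %.3f (n_F/n_D = %.2f), intercept %.3f +/- %.3f\n",
    x$slope, x$slope_se, x$n_f / x$n_d, x$intercept, x$intercept_se))
  cat(sprintf("  E_m = %.1f mV  (dye %.0f mV, nu = %g mV, %d points)\n",
              x$e_m, x$e_dye, x$nernst_slope_mv, x$n_used))
  if (x$slope_warning) cat("  WARNING: slope off n_F/n_D by > 25%\n")
  invisible(x)
}
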