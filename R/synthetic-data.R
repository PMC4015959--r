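#' Ground truth for a dye-coupled reductive equilibration experiment
#'
#' Parameters of a two-couple system — enzyme-bound flavin and a reference
#' dye — reduced by a constant influx of electron equivalents (the
#' xanthine/xanthine-oxidase donor system), with the mediator enforcing
#' instantaneous inter-couple equilibrium.
#'
#' @param e_enz,e_dye Midpoint potentials of the enzyme flavin and the dye, mV.
#' @param n_f,n_d Electrons per couple (1 or 2).
#' @param f_tot,d_tot Total concentrations, µM.
#' @param influx Electron-equivalent influx rate, µM min^-1.
#'
#' @return An `equilibration_truth`.
#' @examples
#' equilibration_truth(e_enz = -138, e_dye = -125)
#' @export
equilibration_truth <- function(e_enz, e_dye, n_f = 2L, n_d = 2L,
                                f_tot = 65, d_tot = 40, influx = 6) {
  if (!n_f %in% c(1L, 2L) || !n_d %in% c(1L, 2L))
    stop("`n_f` and `n_d` must be 1 or 2")
  if (f_tot <= 0 || d_tot <= 0) stop("totals must be > 0")
  if (influx <= 0) stop("`influx` must be > 0")
  structure(list(e_enz = e_enz, e_dye = e_dye, n_f = as.integer(n_f),
                 n_d = as.integer(n_d), f_tot = f_tot, d_tot = d_tot,
                 influx = influx),
            class = "equilibration_truth")
}

#' @export
print.equilibration_truth <- function(x, ...) {
  cat(sprintf(
    "<equilibration_truth> E_enz %g mV (n=%d), E_dye %g mV (n=%d), F %g uM, D %g uM, influx %g uM/min\n",
    x$e_enz, x$n_f, x$e_dye, x$n_d, x$f_tot, x$d_tot, x$influx))
  invisible(x)
}

# Exact single-site bound-ligand concentration from the quadratic
# mass balance; P, L, kd in the same concentration unit.
bound_ligand <- function(p_tot, l_tot, kd) {
  s <- p_tot + l_tot + kd
  disc <- s^2 - 4 * p_tot * l_tot
  disc[disc < 0] <- 0  # guard tiny negative from roundoff
  (s - sqrt(disc)) / 2
}

#' Default apoprotein titration schedule
#'
#' Twelve titrant levels from 0 to 1 µM, sampled densely at low
#' concentrations where the tight-binding transition carries the
#' information, as in a manual cuvette titration.
#'
#' @return Numeric vector of apoprotein concentrations, µM.
#' @export
titration_design <- function() {
  c(0, 0.02, 0.04, 0.06, 0.08, 0.10, 0.14, 0.20, 0.30, 0.45, 0.70, 1.00)
}

#' Simulate a fluorescence-quenching titration
#'
#' Apoprotein is titrated into a fixed total flavin concentration; bound
#' flavin is the exact root of the single-site quadratic mass balance and the
#' emission is a linear combination of free and bound flavin with
#' per-species brightness coefficients. Binding quenches, so by default
#' `f_bound < f_free`.
#'
#' @param kd Dissociation constant, nM.
#' @param protein_series Apoprotein concentrations, µM.
#' @param flavin_total Total flavin, nM.
#' @param f_free,f_bound Emission per nM of free / bound flavin.
#' @param cfg A [sim_config()].
#' @param quenching If `TRUE` (default) require `f_bound <= f_free`.
#'
#' @return A [titration_curve()] with attribute `truth` recording the inputs.
#' @examples
#' gen_titration(kd = 27, cfg = sim_config(seed = 1, noise_rel = 0.02))
#' @export
gen_titration <- function(kd, protein_series = titration_design(),
                          flavin_total = 100, f_free = 10, f_bound = 1.5,
                          cfg = sim_config(), quenching = TRUE) {
  .assert_config(cfg)
  if (kd < 0 || flavin_total <= 0 || any(protein_series < 0))
    stop("concentrations must be non-negative and `flavin_total` > 0")
  if (quenching && f_bound > f_free)
    stop("quenching mode requires f_bound <= f_free")
  p_nm <- protein_series * 1000  # uM -> nM
  bound <- bound_ligand(p_nm, flavin_total, kd)
  emission <- f_free * (flavin_total - bound) + f_bound * bound
  .seed_rng(cfg)
  emission <- .apply_noise(emission, cfg)
  out <- titration_curve(protein_series, emission, flavin_total = flavin_total)
  attr(out, "truth") <- list(kd = kd, f_free = f_free, f_bound = f_bound,
                             seed = cfg$seed, noise_rel = cfg$noise_rel)
  out
}

# Reduced fraction of an n-electron couple at solution potential e_h (mV).
.frac_reduced <- function(e_h, e_mid, n, nu = 59) {
  1 / (1 + 10^(n * (e_h - e_mid) / nu))
}

# Solve for the common solution potential at which the delivered electron
# equivalents q are partitioned between the two couples (bisection).
.solve_potential <- function(q, truth, nu = 59) {
  cap <- truth$n_f * truth$f_tot + truth$n_d * truth$d_tot
  if (q <= 0) return(Inf)      # fully oxidized
  if (q >= cap) return(-Inf)   # fully reduced
  f <- function(e) {
    truth$n_f * truth$f_tot * .frac_reduced(e, truth$e_enz, truth$n_f, nu) +
      truth$n_d * truth$d_tot * .frac_reduced(e, truth$e_dye, truth$n_d, nu) - q
  }
  lo <- min(truth$e_enz, truth$e_dye) - 600
  hi <- max(truth$e_enz, truth$e_dye) + 600
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}

#' Simulate a dye-coupled reductive equilibration time course
#'
#' Electron equivalents are delivered at a constant rate and instantaneously
#' partitioned between the enzyme flavin couple and the dye couple so that
#' both sit at a common solution potential (Nernstian equilibrium enforced by
#' the mediator). Absorbances at the analysis wavelengths are extinction-
#' weighted sums over the four species.
#'
#' @param truth An [equilibration_truth()].
#' @param eps An [extinction_matrix()].
#' @param times Sampling times, minutes, increasing from 0.
#' @param cfg A [sim_config()].
#' @param path_length Optical path, cm.
#' @param nernst_slope_mv Nernst slope, mV per decade.
#'
#' @return An [absorbance_series()] with attribute `truth` carrying the
#'   parameters and the exact species fractions at each time.
#' @export
gen_equilibration <- function(truth, eps = extinction_matrix(),
                              times = seq(0, 40, by = 2.5),
                              cfg = sim_config(), path_length = 1,
                              nernst_slope_mv = 59) {
  .assert_config(cfg)
  if (!inherits(truth, "equilibration_truth"))
    stop("`truth` must be an equilibration_truth")
  times <- as.numeric(times)
  if (times[1] < 0 || is.unsorted(times, strictly = TRUE))
    stop("`times` must be increasing and start at >= 0")
  cap <- truth$n_f * truth$f_tot + truth$n_d * truth$d_tot
  q <- pmin(truth$influx * times, cap)
  e_h <- vapply(q, .solve_potential, numeric(1), truth = truth,
                nu = nernst_slope_mv)
  fr_f <- .frac_reduced(e_h, truth$e_enz, truth$n_f, nernst_slope_mv)
  fr_d <- .frac_reduced(e_h, truth$e_dye, truth$n_d, nernst_slope_mv)
  # saturation endpoints where e_h is +-Inf
  fr_f[q <= 0] <- 0; fr_d[q <= 0] <- 0
  fr_f[q >= cap] <- 1; fr_d[q >= cap] <- 1
  conc <- cbind(flavin_ox = truth$f_tot * (1 - fr_f),
                flavin_red = truth$f_tot * fr_f,
                dye_ox = truth$d_tot * (1 - fr_d),
                dye_red = truth$d_tot * fr_d)  # uM
  a_clean <- (conc / 1000) %*% eps$eps * path_length  # mM * (mM^-1 cm^-1) * cm
  .seed_rng(cfg)
  a_noisy <- matrix(.apply_noise(as.vector(a_clean), cfg), nrow = nrow(a_clean),
                    dimnames = dimnames(a_clean))
  out <- absorbance_series(times, a_noisy, f_tot = truth$f_tot,
                           d_tot = truth$d_tot, path_length = path_length,
                           wavelengths = eps$wavelengths)
  attr(out, "truth") <- list(truth = truth, e_h = e_h,
                             frac_red_enzyme = fr_f, frac_red_dye = fr_d,
                             seed = cfg$seed, noise_rel = cfg$noise_rel)
  out
}

#' Simulate Michaelis-Menten initial-rate data
#'
#' @param km Michaelis constant, µM.
#' @param kcat Catalytic constant, s^-1.
#' @param e_tot Enzyme concentration, µM.
#' @param s_series Substrate concentrations, µM.
#' @param cfg A [sim_config()].
#'
#' @return A [rate_dataset()] with attribute `truth`.
#' @export
gen_rates_mm <- function(km, kcat, e_tot = 0.005,
                         s_series = c(2, 5, 10, 15, 22, 35, 50, 100, 250, 500),
                         cfg = sim_config()) {
  .assert_config(cfg)
  if (km <= 0 || kcat <= 0) stop("`km` and `kcat` must be > 0")
  v <- kcat * e_tot * s_series / (km + s_series)
  .seed_rng(cfg)
  v <- .apply_noise(v, cfg)
  out <- rate_dataset(s_series, v, enzyme_total = e_tot)
  attr(out, "truth") <- list(km = km, kcat = kcat, seed = cfg$seed,
                             noise_rel = cfg$noise_rel)
  out
}

#' Simulate bi-bi ping-pong initial-rate data
#'
#' Rate law \eqn{v = k_{cat} E_0 A B / (K_a B + K_b A + A B)}: substituted-
#' enzyme mechanism with no ternary-complex term, giving parallel
#' double-reciprocal lines.
#'
#' @param kcat Catalytic constant, s^-1.
#' @param ka Michaelis constant of substrate A (NADH), µM.
#' @param kb Michaelis constant of substrate B (flavin), µM.
#' @param e_tot Enzyme concentration, µM.
#' @param a_series Varied A concentrations, µM.
#' @param b_levels Fixed B levels, µM (the standard design uses 10, 20, 50
#'   and 100 µM flavin).
#' @param cfg A [sim_config()].
#'
#' @return A [pingpong_dataset()] with attribute `truth`.
#' @export
gen_rates_pingpong <- function(kcat, ka, kb, e_tot = 0.018,
                               a_series = c(5, 10, 20, 33, 50, 100, 200, 400),
                               b_levels = c(10, 20, 50, 100),
                               cfg = sim_config()) {
  .assert_config(cfg)
  if (kcat <= 0 || ka <= 0 || kb <= 0) stop("kinetic constants must be > 0")
  grid <- expand.grid(A_uM = a_series, B_uM = b_levels)
  v <- kcat * e_tot * grid$A_uM * grid$B_uM /
    (ka * grid$B_uM + kb * grid$A_uM + grid$A_uM * grid$B_uM)
  .seed_rng(cfg)
  v <- .apply_noise(v, cfg)
  out <- pingpong_dataset(grid$A_uM, grid$B_uM, v, enzyme_total = e_tot)
  attr(out, "truth") <- list(kcat = kcat, ka = ka, kb = kb, seed = cfg$seed,
                             noise_rel = cfg$noise_rel)
  out
}

#' Simulate initial-rate data under a ternary-complex (sequential) rate law
#'
#' Negative control for the parallel-lines diagnostic:
#' \eqn{v = k_{cat} E_0 A B / (K_{ia} K_b + K_a B + K_b A + A B)} produces
#' intersecting double-reciprocal lines.
#'
#' @inheritParams gen_rates_pingpong
#' @param kia Dissociation constant of the EA complex, µM.
#' @return A [pingpong_dataset()] with attribute `truth`.
#' @export
gen_rates_ternary <- function(kcat, ka, kb, kia, e_tot = 0.018,
                              a_series = c(5, 10, 20, 33, 50, 100, 200, 400),
                              b_levels = c(10, 20, 50, 100),
                              cfg = sim_config()) {
  .assert_config(cfg)
  if (any(c(kcat, ka, kb, kia) <= 0)) stop("kinetic constants must be > 0")
  grid <- expand.grid(A_uM = a_series, B_uM = b_levels)
  v <- kcat * e_tot * grid$A_uM * grid$B_uM /
    (kia * kb + ka * grid$B_uM + kb * grid$A_uM + grid$A_uM * grid$B_uM)
  .seed_rng(cfg)
  v <- .apply_noise(v, cfg)
  out <- pingpong_dataset(grid$A_uM, grid$B_uM, v, enzyme_total = e_tot)
  attr(out, "truth") <- list(kcat = kcat, ka = ka, kb = kb, kia = kia,
                             seed = cfg$seed, noise_rel = cfg$noise_rel)
  out
}

#' Simulate a stopped-flow single-exponential decay trace
#'
#' @param kobs Observed rate constant, s^-1.
#' @param amplitude Absorbance amplitude of the decay.
#' @param offset Final (baseline) absorbance.
#' @param dt Sampling interval, s.
#' @param n Number of points.
#' @param cfg A [sim_config()].
#' @param nadh Post-mix NADH concentration, µM (metadata).
#'
#' @return A [stopped_flow_trace()] with attribute `truth`.
#' @export
gen_trace <- function(kobs, amplitude = 0.35, offset = 0.05,
                      dt = NULL, n = 200L, cfg = sim_config(),
                      nadh = NA_real_) {
  .assert_config(cfg)
  if (kobs < 0) stop("`kobs` must be >= 0")
  n <- as.integer(n)
  if (is.null(dt)) {
    # sample ~8 decay lifetimes; flat traces get a 1 s window
    dt <- if (kobs > 0) 8 / kobs / n else 1 / n
  }
  t <- dt * seq(0, n - 1L)
  a <- offset + amplitude * exp(-kobs * t)
  .seed_rng(cfg)
  a <- .apply_noise(a, cfg)
  out <- stopped_flow_trace(t, a, nadh = nadh)
  attr(out, "truth") <- list(kobs = kobs, amplitude = amplitude,
                             offset = offset, seed = cfg$seed,
                             noise_rel = cfg$noise_rel)
  out
}

#' Homogeneous-sphere form factor intensity
#'
#' \eqn{I(q) = R^6 [3(\sin qR - qR\cos qR)/(qR)^3]^2}, the analytic
#' scattering intensity of a uniform sphere of radius R, volume-squared
#' weighted (forward scattering scales with particle volume squared).
#'
#' @param q Scattering vector, Å^-1.
#' @param radius Sphere radius, Å.
#' @return Intensities (arbitrary units) at each `q`.
#' @export
sphere_form_factor <- function(q, radius) {
  x <- q * radius
  # series below x ~ 0.05: the closed form loses precision to cancellation
  amp <- ifelse(x < 0.05,
                1 - x^2 / 10 + x^4 / 280,
                3 * (sin(x) - x * cos(x)) / pmax(x, 1e-300)^3)
  radius^6 * amp^2
}

#' Simulate a scattering curve from a sphere mixture
#'
#' @param weights Non-negative volume fractions summing to 1.
#' @param radii One sphere radius (Å) per component; defaults approximate a
#'   ~43 kDa dimer and ~85 kDa tetramer of a small flavoprotein.
#' @param q Scattering vector grid, Å^-1.
#' @param scale Overall intensity scale.
#' @param cfg A [sim_config()]; `noise_rel` sets the per-point relative
#'   uncertainty reported in the `sigma` column.
#'
#' @return A list with elements `curve` (a [scattering_curve()]) and
#'   `components` (a [form_factor_set()]), plus attribute `truth`.
#' @export
gen_saxs_mixture <- function(weights, radii = c(dimer = 23, tetramer = 29),
                             q = seq(0.008, 0.2, length.out = 120),
                             scale = 1, cfg = sim_config()) {
  .assert_config(cfg)
  weights <- as.numeric(weights)
  if (any(weights < 0)) stop("`weights` must be >= 0")
  if (abs(sum(weights) - 1) > 1e-8) stop("`weights` must sum to 1")
  if (length(weights) != length(radii))
    stop("one radius per mixture weight")
  comp <- vapply(radii, function(r) sphere_form_factor(q, r),
                 numeric(length(q)))
  colnames(comp) <- if (!is.null(names(radii))) names(radii) else
    paste0("component", seq_along(radii))
  i_clean <- scale * as.vector(comp %*% weights)
  .seed_rng(cfg)
  i_noisy <- .apply_noise(i_clean, cfg)
  sig_rel <- max(cfg$noise_rel, 1e-4)  # honest floor for noiseless curves
  sigma <- sig_rel * i_clean + cfg$noise_abs
  out <- list(curve = scattering_curve(q, i_noisy, sigma),
              components = form_factor_set(q, comp))
  attr(out, "truth") <- list(weights = weights, radii = radii, scale = scale,
                             seed = cfg$seed, noise_rel = cfg$noise_rel)
  out
}
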