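test_that("identical seed and parameters give bit-identical output", {
  cfg <- function() sim_config(seed = 11, noise_rel = 0.02)
  expect_identical(gen_titration(27, cfg = cfg()),
                   gen_titration(27, cfg = cfg()))
  tr <- equilibration_truth(-138, -125)
  expect_identical(gen_equilibration(tr, cfg = cfg()),
                   gen_equilibration(tr, cfg = cfg()))
  expect_identical(gen_rates_mm(22, 258, cfg = cfg()),
                   gen_rates_mm(22, 258, cfg = cfg()))
  expect_identical(gen_rates_pingpong(50, 33, 111, cfg = cfg()),
                   gen_rates_pingpong(50, 33, 111, cfg = cfg()))
  expect_identical(gen_trace(147, cfg = cfg()), gen_trace(147, cfg = cfg()))
  expect_identical(gen_saxs_mixture(c(0.5, 0.5), cfg = cfg()),
                   gen_saxs_mixture(c(0.5, 0.5), cfg = cfg()))
})

test_that("titration generator honours binding limits", {
  # stoichiometric limit: kd = 0 and excess protein binds all flavin
  crv <- gen_titration(kd = 0, protein_series = c(0.1, 0.2, 0.5, 1),
                       f_free = 10, f_bound = 1.5)
  expect_equal(crv$emission, rep(1.5 * 100, 4))
  # no titrant: pure free-flavin emission
  crv0 <- gen_titration(kd = 27, protein_series = c(0, 0.1, 0.2, 0.5))
  expect_equal(crv0$emission[1], 10 * 100)
  expect_error(gen_titration(kd = -1), "non-negative")
  expect_error(gen_titration(27, f_free = 1, f_bound = 5), "quenching")
  # enhancement mode is allowed when flagged
  crv_e <- gen_titration(27, f_free = 1, f_bound = 5, quenching = FALSE)
  expect_true(all(diff(crv_e$emission) > 0))
})

test_that("equilibration generator respects endpoints, monotonicity and totals", {
  tr <- equilibration_truth(e_enz = -138, e_dye = -125, f_tot = 65, d_tot = 40)
  eps <- extinction_matrix()
  ser <- gen_equilibration(tr, eps = eps, times = seq(0, 60, 5))
  truth <- attr(ser, "truth")
  # t = 0: fully oxidized, absorbance = oxidized-row extinction times totals
  a0_expect <- (65 * eps$eps["flavin_ox", ] + 40 * eps$eps["dye_ox", ]) / 1000
  expect_equal(unname(ser$absorbance[1, ]), unname(a0_expect))
  # delivered equivalents reach capacity -> both couples fully reduced
  expect_equal(truth$frac_red_enzyme[length(ser$times)], 1)
  expect_equal(truth$frac_red_dye[length(ser$times)], 1)
  # solution potential monotone non-increasing as equivalents accumulate
  # (clamp the +/-Inf endpoint values of the fully oxidized/reduced system)
  e_h <- pmin(pmax(truth$e_h, -1e6), 1e6)
  expect_true(all(diff(e_h) <= 1e-9))
  expect_error(gen_equilibration(tr, times = c(0, 2, 2, 5)), "increasing")
})

test_that("rate-law generators reproduce their closed forms", {
  # Michaelis-Menten limits
  mm <- gen_rates_mm(km = 22, kcat = 258, e_tot = 1,
                     s_series = c(22, 2.2e6, 1, 5, 10))
  expect_equal(mm$v_uM_per_s[1], 258 / 2, tolerance = 1e-12)
  expect_equal(mm$v_uM_per_s[2], 258, tolerance = 1e-4)
  # ping-pong with saturating B collapses to MM in A with K_m = ka
  a <- c(5, 10, 33, 50, 100, 400)
  pp <- gen_rates_pingpong(50, 33, 111, e_tot = 1, a_series = a,
                           b_levels = c(1e7, 2e7, 3e7))
  sub <- pp[pp$B_uM == 1e7, ]
  expect_equal(sub$v_uM_per_s, 50 * sub$A_uM / (33 + sub$A_uM),
               tolerance = 1e-4)
  # parallel-lines property: reciprocal slopes identical across B levels
  pp2 <- gen_rates_pingpong(50, 33, 111, e_tot = 1)
  slopes <- vapply(split(pp2, pp2$B_uM), function(d)
    unname(coef(lm(I(1 / v_uM_per_s) ~ I(1 / A_uM), data = d))[2]),
    numeric(1))
  expect_equal(max(slopes) - min(slopes), 0, tolerance = 1e-10)
  expect_error(gen_rates_mm(km = -5, kcat = 258), "must be > 0")
})

test_that("trace generator covers flat and decayed limits", {
  fl <- gen_trace(kobs = 0, amplitude = 0.3, offset = 0.05, n = 50)
  expect_equal(fl$A450, rep(0.35, 50))
  tc <- gen_trace(kobs = 147, amplitude = 0.3, offset = 0.05, n = 100)
  expect_lt(abs(tc$A450[100] - 0.05), 2e-4)  # ~8 lifetimes sampled
})

test_that("sphere-mixture generator is linear in its components", {
  one <- gen_saxs_mixture(weights = c(1, 0))
  ratio <- one$curve$I / one$components$intensities[, 1]
  expect_equal(max(ratio) - min(ratio), 0, tolerance = 1e-12)
  # forward-scattering limit of the sphere form factor
  expect_equal(sphere_form_factor(1e-8, 23), 23^6, tolerance = 1e-6)
  expect_error(gen_saxs_mixture(weights = c(0.6, 0.6)), "sum to 1")
  expect_error(gen_saxs_mixture(weights = c(-0.1, 1.1)), ">= 0")
})

test_that("every generator round-trips through its fitter without noise", {
  expect_equal(fit_tight_binding(gen_titration(kd = 27))$kd, 27,
               tolerance = 1e-6)
  fm <- fit_mm(gen_rates_mm(22, 258))
  expect_equal(c(fm$km, fm$kcat), c(22, 258), tolerance = 1e-6)
  fp <- fit_pingpong(gen_rates_pingpong(50, 33, 111))
  expect_equal(c(fp$kcat, fp$ka, fp$kb), c(50, 33, 111), tolerance = 1e-6)
  expect_equal(fit_exponential(gen_trace(147))$kobs, 147, tolerance = 1e-6)
  ser <- gen_equilibration(equilibration_truth(-138, -125))
  nf <- equilibration_fit(deconvolve(ser, extinction_matrix()), e_dye = -125)
  expect_equal(nf$slope, 1, tolerance = 1e-6)
  expect_equal(nf$e_m, -138, tolerance = 1e-6)
  sx <- gen_saxs_mixture(c(0.09, 0.91))
  fx <- fit_mixture(sx$curve, sx$components)
  expect_equal(unname(fx$weights), c(0.09, 0.91), tolerance = 1e-6)
})
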