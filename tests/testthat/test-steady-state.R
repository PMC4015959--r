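test_that("A340 slope converts to velocity through the NADH extinction", {
  expect_equal(rate_from_a340(0), 0)
  expect_equal(rate_from_a340(0.373), 1.0, tolerance = 1e-3)
  expect_equal(rate_from_a340(-0.373), 1.0, tolerance = 1e-3)
  expect_equal(rate_from_a340(0.373, path = 2), rate_from_a340(0.373) / 2)
})

test_that("Michaelis-Menten fit recovers parameters and matches its oracle", {
  fm <- fit_mm(gen_rates_mm(22, 258))
  expect_equal(c(fm$km, fm$kcat), c(22, 258), tolerance = 1e-7)
  expect_equal(fm$specificity, 11727.27, tolerance = 1e-4)
  # noisy data against the (km, Vmax) grid oracle
  data <- gen_rates_mm(22, 258, e_tot = 0.005,
                       cfg = sim_config(seed = 9, noise_rel = 0.05))
  fit <- fit_mm(data)
  oracle <- oracle_mm_grid(data, km_grid = seq(15, 30, 0.1),
                           vmax_grid = seq(1.1, 1.5, 0.002))
  expect_equal(fit$km, oracle$km, tolerance = 0.1 / 22)
  expect_equal(fit$kcat * 0.005, oracle$vmax, tolerance = 0.002 / 1.29)
})

test_that("K_m estimation stays within 10% at 5% noise (replicated)", {
  errs <- vapply(1:100, function(s) {
    fit <- fit_mm(gen_rates_mm(22, 258,
                               cfg = sim_config(seed = s, noise_rel = 0.05)))
    abs(fit$km - 22) / 22
  }, numeric(1))
  expect_lt(median(errs), 0.10)
})

test_that("specificity constant matches the tabulated values and scales", {
  expect_equal(specificity(22, 258), 11727, tolerance = 1e-4)
  expect_equal(specificity(40, 196), 4900)
  expect_equal(specificity(1000, 1), 1)
  expect_equal(specificity(22, 258 * 3), 3 * specificity(22, 258))
  expect_error(specificity(0, 1), "> 0")
})

test_that("published variant table is internally consistent after rounding", {
  tab <- check_specificity_table()
  expect_true(all(tab$consistent))
  # and the two benchmark rows reproduce the printed column exactly
  expect_equal(round(specificity(22, 258)), 11727)
  expect_equal(specificity(40, 196), 4900)
})

test_that("ping-pong global fit recovers the engineered-variant parameters", {
  fp <- fit_pingpong(gen_rates_pingpong(50, 33, 111))
  expect_equal(c(fp$kcat, fp$ka, fp$kb), c(50, 33, 111), tolerance = 1e-6)
  expect_lt(fp$parallelism_stat, 1e-8)
  # at 2% noise the fit stays within the printed uncertainties
  fp2 <- fit_pingpong(gen_rates_pingpong(50, 33, 111,
                                         cfg = sim_config(seed = 3,
                                                          noise_rel = 0.02)))
  expect_lt(abs(fp2$kcat - 50), 5)
  expect_lt(abs(fp2$ka - 33), 7)
  expect_lt(abs(fp2$kb - 111), 15)
})

test_that("ternary-complex data break the parallel-lines diagnostic", {
  tern <- gen_rates_ternary(50, 33, 111, kia = 60)
  fp <- suppressWarnings(fit_pingpong(tern))
  expect_gt(fp$parallelism_stat, 0.15)
  expect_true(fp$mechanism_warning)
})

test_that("ping-pong collapses to Michaelis-Menten at saturating cosubstrate", {
  a <- c(5, 10, 20, 33, 50, 100, 200, 400)
  b_sat <- 100 * 111
  pp <- gen_rates_pingpong(50, 33, 111, e_tot = 0.018, a_series = a,
                           b_levels = c(1, 2, 100) * 111)
  mm <- fit_mm(rate_dataset(a, pp$v_uM_per_s[pp$B_uM == b_sat],
                            enzyme_total = 0.018))
  # at fixed B the ping-pong law is exactly MM with apparent constants
  # K_a B/(K_b + B) and k_cat B/(K_b + B) ...
  expect_equal(mm$km, 33 * b_sat / (111 + b_sat), tolerance = 1e-6)
  expect_equal(mm$kcat, 50 * b_sat / (111 + b_sat), tolerance = 1e-6)
  # ... which at B = 100 K_b sit within 1% of the true limiting values
  expect_equal(mm$km, 33, tolerance = 0.01)
  expect_equal(mm$kcat, 50, tolerance = 0.01)
})

test_that("specific-activity conversion and rate ratios", {
  expect_equal(kcat_from_specific_activity(1111, 21412), 396.5,
               tolerance = 1e-4)
  expect_equal(display_round(display_round(
    kcat_from_specific_activity(1111, 21412), 1)), 397)
  expect_equal(kcat_from_specific_activity(0, 50000), 0)
  expect_equal(kcat_from_specific_activity(60, 60000), 60)
  expect_equal(kie(1, 1), 1)
  expect_equal(kie(258, 47.3), 5.45, tolerance = 1e-3)
  expect_equal(kie(147, 77.4), 1.9, tolerance = 1e-2)
  k <- kie(258, 47.3, se_h = 6, se_d = 1.1)
  expect_equal(k$se, 5.45 * sqrt((6 / 258)^2 + (1.1 / 47.3)^2),
               tolerance = 1e-3)
  expect_equal(activity_ratio(1, 1), 1)
  expect_equal(activity_ratio(50, 146), 0.342, tolerance = 1e-2)
  expect_equal(activity_ratio(1.5, 258), 0.006, tolerance = 5e-2)
})
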