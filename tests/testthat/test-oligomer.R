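test_that("SEC calibration recovers a known log-linear relation", {
  # colinear markers give an exact line
  ve <- c(8, 9, 10, 11)
  mk <- sec_marker_table(paste0("m", 1:4), 10^(4.3 - 0.284 * ve), ve)
  cal <- sec_calibrate(mk)
  expect_equal(cal$intercept, 4.3, tolerance = 1e-9)
  expect_equal(cal$slope, -0.284, tolerance = 1e-9)
  expect_equal(cal$r_squared, 1)
  # noisy 4-marker table recovers the line
  set.seed(4)
  mk2 <- sec_marker_table(paste0("m", 1:4),
                          10^(4.3 - 0.284 * ve + rnorm(4, 0, 0.01)), ve)
  cal2 <- sec_calibrate(mk2)
  expect_equal(cal2$slope, -0.284, tolerance = 0.05)
  # non-monotone tables warn
  expect_warning(sec_marker_table(paste0("m", 1:3), c(10, 50, 20), c(8, 9, 10)),
                 "monotone")
})

test_that("apparent mass and subunit count follow the calibration", {
  cal <- sec_calibrate(sec_markers_superose12())
  app <- sec_apparent_mass(cal, 9.5)
  expect_equal(subunit_count(app$mass_da, 21288), 1.88)
  expect_false(app$extrapolated)
  expect_true(sec_apparent_mass(cal, 20)$extrapolated)
  expect_equal(subunit_count(21288, 21288), 1.00)
  expect_equal(subunit_count(40022, 21288), 1.88)
  expect_equal(subunit_count(4 * 21288, 21288), 4.00)
})

test_that("mixture fit identifies a pure component with zero misfit", {
  sx <- gen_saxs_mixture(c(1, 0))
  fit <- fit_mixture(sx$curve, sx$components)
  expect_equal(unname(fit$weights), c(1, 0), tolerance = 1e-9)
  expect_lt(fit$chi, 1e-12)
})

test_that("mixture fit recovers dimer:tetramer volume fractions under noise", {
  sx <- gen_saxs_mixture(c(0.09, 0.91),
                         cfg = sim_config(seed = 21, noise_rel = 0.01))
  fit <- fit_mixture(sx$curve, sx$components)
  expect_lt(max(abs(fit$weights - c(0.09, 0.91))), 0.02)
  expect_equal(sum(fit$weights), 1)
  eq <- gen_saxs_mixture(c(0.5, 0.5),
                         cfg = sim_config(seed = 22, noise_rel = 0.01))
  feq <- fit_mixture(eq$curve, eq$components)
  expect_lt(max(abs(feq$weights - 0.5)), 0.02)
})

test_that("mixture fit equals the exhaustive weight-grid search", {
  sx <- gen_saxs_mixture(c(0.3, 0.7),
                         cfg = sim_config(seed = 8, noise_rel = 0.02))
  fit <- fit_mixture(sx$curve, sx$components)
  oracle <- oracle_mixture_grid(sx$curve, sx$components)
  expect_lt(abs(fit$weights[1] - oracle$w1), 0.01)
  n <- nrow(sx$curve)
  expect_lte(fit$chi * (n - 2), oracle$chi2 + 1e-9)
})

test_that("reduced chi-square is invariant to common intensity rescaling", {
  sx <- gen_saxs_mixture(c(0.25, 0.75),
                         cfg = sim_config(seed = 12, noise_rel = 0.01))
  fit1 <- fit_mixture(sx$curve, sx$components)
  scaled <- scattering_curve(sx$curve$q, sx$curve$I * 1e3,
                             sx$curve$sigma * 1e3)
  fit2 <- fit_mixture(scaled, sx$components)
  expect_equal(fit2$chi, fit1$chi, tolerance = 1e-9)
  expect_equal(fit2$weights, fit1$weights, tolerance = 1e-9)
})

test_that("weight estimates are consistent as noise shrinks", {
  err_at <- function(noise) {
    errs <- vapply(1:12, function(s) {
      sx <- gen_saxs_mixture(c(0.09, 0.91),
                             cfg = sim_config(seed = 100 + s,
                                              noise_rel = noise))
      max(abs(fit_mixture(sx$curve, sx$components)$weights - c(0.09, 0.91)))
    }, numeric(1))
    mean(errs)
  }
  e_hi <- err_at(0.03); e_lo <- err_at(0.003)
  expect_lt(e_lo, e_hi)
  expect_lt(e_lo, 0.005)
})

test_that("component grids are interpolated and degenerate sets flagged", {
  sx <- gen_saxs_mixture(c(0.4, 0.6))
  sub <- scattering_curve(sx$curve$q[5:100], sx$curve$I[5:100],
                          sx$curve$sigma[5:100])
  shifted <- form_factor_set(sx$components$q + 1e-5,
                             sx$components$intensities)
  fit <- fit_mixture(sub, shifted)
  expect_true(fit$interpolated)
  # identical components cannot be apportioned
  dup <- form_factor_set(sx$components$q,
                         cbind(a = sx$components$intensities[, 1],
                               b = sx$components$intensities[, 1]))
  fd <- fit_mixture(sx$curve, dup)
  expect_true(fd$ill_conditioned || any(!is.finite(fd$weights_se)))
})
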