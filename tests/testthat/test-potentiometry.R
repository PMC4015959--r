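test_that("deconvolution handles the trivial and degenerate regimes", {
  # no spectral overlap, fully oxidized sample
  eps <- extinction_matrix(rbind(flavin_ox = c(12.5, 0),
                                 flavin_red = c(0, 0),
                                 dye_ox = c(0, 20),
                                 dye_red = c(0, 0)))
  ser <- gen_equilibration(equilibration_truth(-138, -125, influx = 1e-9),
                           eps = eps, times = c(0, 1, 2))
  fr <- deconvolve(ser, eps)
  expect_equal(fr$f_ox_enzyme, rep(1, 3), tolerance = 1e-9)
  expect_equal(fr$f_ox_dye, rep(1, 3), tolerance = 1e-9)
  # zero absorbance with non-absorbing reduced species means fully reduced
  zer <- absorbance_series(c(0, 1), matrix(0, 2, 2), f_tot = 65, d_tot = 40)
  fr0 <- deconvolve(zer, eps)
  expect_equal(fr0$f_ox_enzyme, c(0, 0))
  expect_equal(fr0$f_ox_dye, c(0, 0))
  # a singular extinction configuration is rejected with a condition report
  bad <- extinction_matrix(rbind(flavin_ox = c(10, 10),
                                 flavin_red = c(0, 0),
                                 dye_ox = c(10, 10),
                                 dye_red = c(0, 0)))
  expect_error(deconvolve(ser, bad), "singular")
})

test_that("deconvolution inverts the generator exactly and re-projects", {
  eps <- extinction_matrix()
  tr <- equilibration_truth(-138, -125)
  ser <- gen_equilibration(tr, eps = eps)
  fr <- deconvolve(ser, eps)
  truth <- attr(ser, "truth")
  expect_equal(fr$f_ox_enzyme, 1 - truth$frac_red_enzyme, tolerance = 1e-9)
  expect_equal(fr$f_ox_dye, 1 - truth$frac_red_dye, tolerance = 1e-9)
  # re-projection through the extinction matrix reproduces the input
  conc <- cbind(tr$f_tot * fr$f_ox_enzyme, tr$f_tot * (1 - fr$f_ox_enzyme),
                tr$d_tot * fr$f_ox_dye, tr$d_tot * (1 - fr$f_ox_dye))
  a_back <- (conc / 1000) %*% eps$eps
  expect_equal(unname(a_back), unname(ser$absorbance), tolerance = 1e-12)
})

test_that("Nernst plot slope equals the electron-number ratio", {
  eps <- extinction_matrix()
  s22 <- gen_equilibration(equilibration_truth(-138, -125, n_f = 2, n_d = 2),
                           eps = eps)
  f22 <- equilibration_fit(deconvolve(s22, eps), e_dye = -125)
  expect_equal(f22$slope, 1, tolerance = 1e-9)
  s21 <- gen_equilibration(equilibration_truth(-138, -125, n_f = 2, n_d = 1),
                           eps = eps)
  f21 <- expect_warning(
    equilibration_fit(deconvolve(s21, eps), e_dye = -125, n_f = 2, n_d = 2),
    "slope")
  f21 <- suppressWarnings(
    equilibration_fit(deconvolve(s21, eps), e_dye = -125, n_f = 2, n_d = 1))
  expect_equal(f21$slope, 2, tolerance = 1e-6)
})

test_that("the intercept carries the midpoint-potential difference", {
  eps <- extinction_matrix()
  ser <- gen_equilibration(equilibration_truth(-138, -125), eps = eps)
  fit <- equilibration_fit(deconvolve(ser, eps), e_dye = -125)
  # closed form: intercept = n_F (E_enz - E_dye) / nu
  expect_equal(fit$intercept, 2 * (-138 - -125) / 59, tolerance = 1e-6)
  expect_equal(fit$e_m, -138, tolerance = 1e-6)
})

test_that("intercept-to-potential arithmetic is exact and affine", {
  expect_equal(potential_from_intercept(-125, -0.45, 2), -138.275)
  expect_equal(display_round(potential_from_intercept(-125, -0.45, 2)), -138)
  expect_equal(potential_from_intercept(-200, 0, 1), -200)
  expect_equal(potential_from_intercept(-252, 0.915, 2), -225.0,
               tolerance = 1e-4)
  b <- seq(-2, 2, 0.25)
  em <- potential_from_intercept(-125, b, 2)
  expect_equal(diff(em) / diff(b), rep(59 / 2, length(b) - 1))
})

test_that("midpoint recovery is exact across dye separations", {
  eps <- extinction_matrix()
  for (sep in c(-150, -60, -13, 25, 90, 150)) {
    e_dye <- -125
    truth <- equilibration_truth(e_dye + sep, e_dye)
    ser <- gen_equilibration(truth, eps = eps,
                             times = seq(0, 40, length.out = 120))
    # widen the fraction window: noiseless log-ratios are exact, and large
    # separations leave few points with both couples mid-transition
    fit <- suppressWarnings(
      equilibration_fit(deconvolve(ser, eps), e_dye = e_dye,
                        window = c(1e-6, 1 - 1e-6)))
    expect_lt(abs(fit$e_m - (e_dye + sep)), 0.1)
  }
  # free-flavin control against the anthraquinone-2-sulfonate reference
  ctrl <- gen_equilibration(equilibration_truth(-212, -225), eps = eps)
  aqs <- dye_lookup("anthraquinone_2_sulfonate")
  fit <- equilibration_fit(deconvolve(ctrl, eps), e_dye = aqs$e_mv,
                           n_d = aqs$n)
  expect_equal(fit$e_m, -212, tolerance = 1e-4)
})

test_that("regression window excludes endpoint blow-ups and enforces n >= 3", {
  eps <- extinction_matrix()
  ser <- gen_equilibration(equilibration_truth(-138, -125), eps = eps,
                           times = c(0, 1, 35, 40, 45))
  expect_error(equilibration_fit(deconvolve(ser, eps), e_dye = -125),
               "fewer than 3")
})

test_that("dye library holds the standard references and is extensible", {
  expect_equal(dye_lookup("indigo_carmine")$e_mv, -125)
  expect_equal(dye_lookup("phenosafranin")$e_mv, -252)
  expect_equal(dye_lookup("anthraquinone_2_sulfonate")$e_mv, -225)
  expect_equal(dye_lookup("anthraquinone_2_sulfonate")$n, 2)
  expect_error(dye_lookup("methylene_blue"), "unknown dye")
  lib <- dye_library(extra = list(methylene_blue = list(e_mv = 11, n = 2),
                                  indigo_carmine = list(e_mv = -120)))
  expect_equal(dye_lookup("methylene_blue", lib)$e_mv, 11)
  expect_equal(dye_lookup("indigo_carmine", lib)$e_mv, -120)
})
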