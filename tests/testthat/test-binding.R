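test_that("tight-binding fit recovers K_d in both affinity regimes", {
  # wild-type FMN regime: K_d comparable to total flavin
  f1 <- fit_tight_binding(gen_titration(kd = 27))
  expect_true(f1$converged)
  expect_equal(f1$kd, 27, tolerance = 1e-6)
  expect_lt(f1$f_bound, f1$f_free)
  # riboflavin regime: K_d far above total flavin (6.58 uM = 6580 nM);
  # titrate far enough to populate the bound state
  crv <- gen_titration(kd = 6580,
                       protein_series = c(0, 0.5, 1, 2, 5, 10, 20, 50, 100))
  f2 <- fit_tight_binding(crv)
  expect_equal(f2$kd, 6580, tolerance = 1e-6)
})

test_that("tight-binding fit agrees with a dense grid-search oracle", {
  crv <- gen_titration(kd = 27, cfg = sim_config(seed = 5, noise_rel = 0.02))
  fit <- fit_tight_binding(crv)
  oracle <- oracle_titration_grid(crv,
                                  kd_grid = seq(10, 60, by = 0.5),
                                  f_free_grid = seq(9.5, 10.5, by = 0.02),
                                  f_bound_grid = seq(1.0, 2.0, by = 0.02))
  expect_equal(fit$kd, oracle$kd, tolerance = 0.5 / 27)
  expect_lte(sum(resid(fit$fit)^2), oracle$rss + 1e-9)
})

test_that("a quench-free titration never yields a spurious finite K_d", {
  crv <- titration_curve(protein_total = c(0, 0.1, 0.3, 0.6, 1),
                         emission = rep(1000, 5))
  fit <- fit_tight_binding(crv)
  expect_false(fit$converged && !fit$kd_upper_limit && is.finite(fit$kd))
})

test_that("K_d recovery stays accurate at 2% noise across the binding range", {
  # replicated study spanning 0.1x to 10x the total flavin concentration
  errs <- unlist(lapply(c(10, 27, 100, 400, 1000), function(kd) {
    vapply(1:20, function(s) {
      fit <- fit_tight_binding(
        gen_titration(kd = kd,
                      protein_series = c(titration_design(), 2, 5, 12),
                      cfg = sim_config(seed = s, noise_rel = 0.02)))
      abs(fit$kd - kd) / kd
    }, numeric(1))
  }))
  expect_lt(median(errs), 0.05)
})

test_that("Gibbs conversion follows RT ln Kd on the 1 M standard state", {
  expect_equal(gibbs_from_kd(27e-9)$dg_b, -43.2, tolerance = 1e-3)
  expect_equal(gibbs_from_kd(1)$dg_b, 0)
  expect_equal(gibbs_from_kd(6.58e-6)$dg_b, -29.6, tolerance = 1e-2)
  expect_error(gibbs_from_kd(0), "> 0")
  # strictly increasing in kd, additive on the log scale
  kds <- 10^seq(-9, -3, length.out = 7)
  dgs <- vapply(kds, function(k) gibbs_from_kd(k)$dg_b, numeric(1))
  expect_true(all(diff(dgs) > 0))
  expect_equal(gibbs_from_kd(1e-6)$dg_b + gibbs_from_kd(1e-3)$dg_b,
               gibbs_from_kd(1e-9)$dg_b, tolerance = 1e-12)
})

test_that("delta-delta-G quantifies weakened binding with sign convention", {
  wt <- gibbs_from_kd(27e-9)
  expect_equal(delta_delta_g(wt, wt), 0)
  # tenfold Kd increase costs RT ln 10
  expect_equal(delta_delta_g(gibbs_from_kd(270e-9), wt), 5.71,
               tolerance = 1e-2)
  # phosphate contribution from the FMN/riboflavin ligand pair
  expect_equal(delta_delta_g(gibbs_from_kd(6.58e-6), wt), 13.6,
               tolerance = 5e-2)
  expect_error(delta_delta_g(gibbs_from_kd(1e-6, 310), wt), "temperature")
})

test_that("fold change and additivity arithmetic", {
  expect_equal(round(fold_change(6.58e-6, 27e-9)), 244)
  expect_equal(fold_change(1e-6, 1e-6), 1)
  expect_equal(fold_change(10, 2), 5)
  expect_equal(additivity_check(list(-10, -5), -12), -3)
  expect_equal(additivity_check(list(-10, -5), -15), 0)
  # gibbs_result inputs are accepted and summed directly
  parts <- list(gibbs_from_kd(1e-6), gibbs_from_kd(1e-5))
  brute <- gibbs_from_kd(1e-6)$dg_b + gibbs_from_kd(1e-5)$dg_b
  expect_equal(additivity_check(parts, 0), brute)
})
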