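# Brute-force grid oracles, independent of the package's fitting paths.
# Each scans a dense parameter grid and returns the least-squares optimum.

oracle_titration_grid <- function(curve, kd_grid, f_free_grid, f_bound_grid) {
  l <- attr(curve, "flavin_total")
  p <- curve$protein_uM * 1000
  y <- curve$emission
  best <- list(rss = Inf)
  for (kd in kd_grid) {
    s <- p + l + kd
    cc <- (s - sqrt(pmax(s^2 - 4 * p * l, 0))) / 2
    for (ff in f_free_grid) for (fb in f_bound_grid) {
      rss <- sum((y - ff * (l - cc) - fb * cc)^2)
      if (rss < best$rss) best <- list(rss = rss, kd = kd, ff = ff, fb = fb)
    }
  }
  best
}

oracle_mm_grid <- function(data, km_grid, vmax_grid) {
  s <- data$S_uM; v <- data$v_uM_per_s
  best <- list(rss = Inf)
  for (km in km_grid) for (vm in vmax_grid) {
    rss <- sum((v - vm * s / (km + s))^2)
    if (rss < best$rss) best <- list(rss = rss, km = km, vmax = vm)
  }
  best
}

oracle_exp_grid <- function(trace, k_grid, amp_grid, off_grid) {
  t <- trace$t_s; a <- trace$A450
  best <- list(rss = Inf)
  for (k in k_grid) {
    e <- exp(-k * t)
    for (am in amp_grid) for (of in off_grid) {
      rss <- sum((a - of - am * e)^2)
      if (rss < best$rss) best <- list(rss = rss, k = k, amp = am, off = of)
    }
  }
  best
}

# Two-component mixture oracle: weight grid with the scale profiled in
# closed form (it enters linearly).
oracle_mixture_grid <- function(curve, components, w_grid = seq(0, 1, 0.01)) {
  i1 <- components$intensities[, 1]
  i2 <- components$intensities[, 2]
  y <- curve$I; sg <- curve$sigma
  best <- list(chi2 = Inf)
  for (w in w_grid) {
    m <- w * i1 + (1 - w) * i2
    c_opt <- sum(y * m / sg^2) / sum(m^2 / sg^2)
    chi2 <- sum(((y - c_opt * m) / sg)^2)
    if (chi2 < best$chi2) best <- list(chi2 = chi2, w1 = w, scale = c_opt)
  }
  best
}
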