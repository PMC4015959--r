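#' Build a validated pipeline run configuration
#'
#' @param analysis One of `"titrate"`, `"potentiometry"`, `"mm"`,
#'   `"pingpong"`, `"stopflow"`, `"sec"`, `"saxs_mix"`.
#' @param inputs Named list of input file paths (checked for existence).
#' @param params Named list of parameter overrides understood by the
#'   selected analysis (e.g. `flavin_total_nM`, `temperature_K`, `dye`,
#'   `n_f`, `n_d`, `nernst_slope_mv`, `f_tot`, `d_tot`, `enzyme_total`,
#'   `monomer_mass`, `elution_ml`). Unknown keys are rejected.
#' @param out_dir Output directory (created if missing).
#' @param seed Integer seed recorded in the run log.
#' @return A `run_config`.
#' @export
run_config <- function(analysis, inputs = list(), params = list(),
                       out_dir = tempfile("flavochar_run_"), seed = 1L) {
  analyses <- c("titrate", "potentiometry", "mm", "pingpong", "stopflow",
                "sec", "saxs_mix")
  analysis <- match.arg(analysis, analyses)
  known <- c("flavin_total_nM", "temperature_K", "dye", "e_dye", "n_f",
             "n_d", "nernst_slope_mv", "window", "f_tot", "d_tot",
             "path_length", "dye_wavelength", "enzyme_total", "acceptor",
             "acceptor_conc", "monomer_mass", "elution_ml", "dead_time")
  bad <- setdiff(names(params), known)
  if (length(bad))
    stop("unknown parameter keys: ", paste(bad, collapse = ", "))
  for (p in unlist(inputs))
    if (!file.exists(p)) stop("input path does not exist: ", p)
  structure(list(analysis = analysis, inputs = inputs, params = params,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

.param <- function(config, key, default) config$params[[key]] %||% default

#' Execute a configured analysis and write a report bundle
#'
#' Runs the selected module on the configured inputs and writes machine-
#' readable results (`result.json`), tabular output (`result.csv` where the
#' analysis produces a table), a diagnostic plot (`plot.pdf`) and a run log
#' recording the package version, seed and every effective parameter.
#'
#' @param config A [run_config()].
#' @return The fitted result object, invisibly; its summary list is also
#'   written to `result.json`.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(config$seed)
  p <- config$params
  res <- switch(config$analysis,
    titrate = {
      crv <- read_titration_csv(config$inputs$titration,
                                flavin_total_nM = .param(config, "flavin_total_nM", 100),
                                temperature_K = .param(config, "temperature_K", 298.15))
      fit <- fit_tight_binding(crv)
      gb <- if (fit$converged && !fit$kd_upper_limit)
        gibbs_from_kd(fit$kd * 1e-9, attr(crv, "temperature")) else NULL
      .plot_pdf(file.path(config$out_dir, "plot.pdf"),
                function() .plot_titration(crv, fit))
      summ <- list(kd_nM = fit$kd, kd_se_nM = fit$kd_se,
                   f_free = fit$f_free, f_bound = fit$f_bound,
                   dg_b_kJ_mol = if (is.null(gb)) NA else gb$dg_b,
                   converged = fit$converged)
      utils::write.csv(as.data.frame(summ),
                       file.path(config$out_dir, "result.csv"),
                       row.names = FALSE)
      list(fit = fit, summary = summ)
    },
    potentiometry = {
      dye_name <- .param(config, "dye", "indigo_carmine")
      dye <- dye_lookup(dye_name)
      series <- read_potentiometry_csv(
        config$inputs$series,
        f_tot = .param(config, "f_tot", 65),
        d_tot = .param(config, "d_tot", 40),
        path_length = .param(config, "path_length", 1),
        dye_wavelength = .param(config, "dye_wavelength", 610))
      fr <- deconvolve(series, extinction_matrix())
      fit <- equilibration_fit(fr,
                               e_dye = .param(config, "e_dye", dye$e_mv),
                               n_f = .param(config, "n_f", 2L),
                               n_d = .param(config, "n_d", dye$n),
                               window = .param(config, "window", c(0.1, 0.9)),
                               nernst_slope_mv = .param(config, "nernst_slope_mv", 59))
      .plot_pdf(file.path(config$out_dir, "plot.pdf"),
                function() .plot_nernst(fit))
      utils::write.csv(fit$regression,
                       file.path(config$out_dir, "result.csv"),
                       row.names = FALSE)
      list(fit = fit,
           summary = list(slope = fit$slope, intercept = fit$intercept,
                          e_m_mV = fit$e_m, dye = dye_name,
                          n_points = fit$n_used))
    },
    mm = {
      data <- read_rates_csv(config$inputs$rates,
                             enzyme_total = .param(config, "enzyme_total", 0.005),
                             acceptor = .param(config, "acceptor", "UQ-0"),
                             acceptor_conc = .param(config, "acceptor_conc", 100))
      fit <- fit_mm(data)
      .plot_pdf(file.path(config$out_dir, "plot.pdf"),
                function() .plot_mm(data, fit))
      summ <- list(km_uM = fit$km, km_se = fit$km_se,
                   kcat_s = fit$kcat, kcat_se = fit$kcat_se,
                   specificity_mM_s = fit$specificity,
                   specificity_se = fit$specificity_se)
      utils::write.csv(as.data.frame(summ),
                       file.path(config$out_dir, "result.csv"),
                       row.names = FALSE)
      list(fit = fit, summary = summ)
    },
    pingpong = {
      data <- read_pingpong_csv(config$inputs$rates,
                                enzyme_total = .param(config, "enzyme_total", 0.018))
      fit <- fit_pingpong(data)
      .plot_pdf(file.path(config$out_dir, "plot.pdf"),
                function() .plot_pingpong(data, fit))
      summ <- list(kcat_s = fit$kcat, kcat_se = fit$kcat_se,
                   ka_uM = fit$ka, ka_se = fit$ka_se,
                   kb_uM = fit$kb, kb_se = fit$kb_se,
                   parallelism_stat = fit$parallelism_stat)
      utils::write.csv(as.data.frame(summ),
                       file.path(config$out_dir, "result.csv"),
                       row.names = FALSE)
      list(fit = fit, summary = summ)
    },
    stopflow = {
      paths <- config$inputs$traces
      manifest <- config$inputs$manifest
      nadh <- if (!is.null(manifest)) {
        mf <- utils::read.csv(manifest)
        stats::setNames(mf$nadh_uM, mf$file)
      } else NULL
      fits <- lapply(paths, function(pp) {
        tr <- read_trace_csv(pp, nadh = if (!is.null(nadh))
          nadh[[basename(pp)]] else NA_real_)
        list(trace = tr,
             fit = fit_exponential(tr, dead_time = .param(config, "dead_time", 0)))
      })
      tab <- data.frame(
        file = basename(unlist(paths)),
        nadh_uM = vapply(fits, function(f) attr(f$trace, "nadh"), numeric(1)),
        kobs = vapply(fits, function(f) f$fit$kobs, numeric(1)),
        kobs_se = vapply(fits, function(f) f$fit$kobs_se %||% NA_real_,
                         numeric(1)))
      hyper <- if (all(is.finite(tab$nadh_uM)) && nrow(tab) >= 4)
        fit_kobs_hyperbola(tab[, c("nadh_uM", "kobs")]) else NULL
      utils::write.csv(tab, file.path(config$out_dir, "result.csv"),
                       row.names = FALSE)
      list(fits = fits, table = tab, hyperbola = hyper,
           summary = list(
             k_max_s = if (is.null(hyper)) NA else hyper$k_max,
             k_half_uM = if (is.null(hyper)) NA else hyper$k_half,
             n_traces = nrow(tab)))
    },
    sec = {
      markers <- read_markers_csv(config$inputs$markers)
      cal <- sec_calibrate(markers)
      ve <- .param(config, "elution_ml", NULL)
      if (is.null(ve)) stop("sec analysis needs params$elution_ml")
      app <- sec_apparent_mass(cal, ve)
      mono <- .param(config, "monomer_mass", NULL)
      nsub <- if (!is.null(mono)) subunit_count(app$mass_da, mono) else NA
      list(calibration = cal,
           summary = list(apparent_mass_da = app$mass_da,
                          extrapolated = app$extrapolated,
                          subunits = nsub))
    },
    saxs_mix = {
      curve <- read_saxs_dat(config$inputs$curve)
      comps <- read_form_factors(unlist(config$inputs$form_factors))
      fit <- fit_mixture(curve, comps)
      summ <- c(as.list(fit$weights),
                list(chi = fit$chi, scale = fit$scale))
      utils::write.csv(data.frame(component = names(fit$weights),
                                  weight = unname(fit$weights),
                                  se = unname(fit$weights_se)),
                       file.path(config$out_dir, "result.csv"),
                       row.names = FALSE)
      list(fit = fit, summary = summ)
    })
  jsonlite::write_json(res$summary, file.path(config$out_dir, "result.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  log <- list(package = "flavochar",
              version = as.character(utils::packageVersion("flavochar")),
              analysis = config$analysis, seed = config$seed,
              params = config$params,
              inputs = lapply(config$inputs, function(x) unname(unlist(x))),
              timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(log, file.path(config$out_dir, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(res)
}

.plot_pdf <- function(path, fun) {
  grDevices::pdf(path, width = 6, height = 5)
  on.exit(grDevices::dev.off())
  try(fun(), silent = TRUE)
  invisible(path)
}

.plot_titration <- function(crv, fit) {
  plot(crv$protein_uM, crv$emission, pch = 19,
       xlab = "apoprotein (uM)", ylab = "emission (a.u.)",
       main = "Fluorescence-quenching titration")
  if (isTRUE(fit$converged)) {
    l <- attr(crv, "flavin_total")
    px <- seq(0, max(crv$protein_uM), length.out = 200)
    cc <- bound_ligand(px * 1000, l, fit$kd)
    lines(px, fit$f_free * (l - cc) + fit$f_bound * cc, col = 2)
  }
}

.plot_nernst <- function(fit) {
  plot(fit$regression$log_rd_ox_dye, fit$regression$log_rd_ox_enzyme,
       pch = 19, xlab = "log10(red/ox) dye", ylab = "log10(red/ox) enzyme",
       main = sprintf("Nernst equilibration plot (E_m = %.1f mV)", fit$e_m))
  abline(fit$intercept, fit$slope, col = 2)
}

.plot_mm <- function(data, fit) {
  plot(data$S_uM, data$v_uM_per_s, pch = 19, xlab = "S (uM)",
       ylab = "v (uM/s)", main = "Michaelis-Menten fit")
  if (isTRUE(fit$converged)) {
    sx <- seq(0, max(data$S_uM), length.out = 200)
    lines(sx, fit$kcat * attr(data, "enzyme_total") * sx / (fit$km + sx),
          col = 2)
  }
}

.plot_pingpong <- function(data, fit) {
  # double-reciprocal diagnostic panel: parallel lines under ping-pong
  cols <- seq_along(unique(data$B_uM))
  names(cols) <- sort(unique(data$B_uM))
  plot(1 / data$A_uM, 1 / data$v_uM_per_s,
       col = cols[as.character(data$B_uM)], pch = 19,
       xlab = "1/[A] (uM^-1)", ylab = "1/v (s uM^-1)",
       main = "Double-reciprocal diagnostic")
  e0 <- attr(data, "enzyme_total")
  if (isTRUE(fit$converged)) {
    for (b in as.numeric(names(cols))) {
      ax <- seq(min(data$A_uM), max(data$A_uM), length.out = 100)
      vv <- fit$kcat * e0 * ax * b / (fit$ka * b + fit$kb * ax + ax * b)
      lines(1 / ax, 1 / vv, col = cols[as.character(b)])
    }
  }
  legend("topleft", legend = paste(names(cols), "uM"), col = cols, pch = 19,
         title = "[B]", bty = "n")
}

#' Write a complete synthetic fixture tree
#'
#' Generates one dataset per analysis at the characteristic study design
#' values (27 nM titration at 100 nM flavin; -138/-125 mV equilibration;
#' 22 µM / 258 s^-1 single-substrate kinetics; 50 s^-1, 33 µM, 111 µM
#' ping-pong design at flavin 10/20/50/100 µM; 147 s^-1 stopped-flow
#' hyperbola with 6.4 µM half-saturation; Superose-12 markers; 9:91
#' dimer:tetramer sphere mixture), together with `manifest.json` recording
#' the ground truth and the seed.
#'
#' @param out_dir Directory to create.
#' @param seed Integer seed.
#' @param noise_rel Relative noise for every generated dataset.
#' @return Invisibly, the manifest list.
#' @export
make_fixtures <- function(out_dir, seed = 1L, noise_rel = 0.02) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(seed)
  truth <- list(seed = seed, noise_rel = noise_rel)

  cfg <- function(off) sim_config(seed = seed + off, noise_rel = noise_rel)

  crv <- gen_titration(kd = 27, cfg = cfg(1L))
  write_titration_csv(crv, file.path(out_dir, "titration.csv"))
  truth$titration <- list(kd_nM = 27, flavin_total_nM = 100)

  eq_truth <- equilibration_truth(e_enz = -138, e_dye = -125)
  series <- gen_equilibration(eq_truth, cfg = cfg(2L))
  write_potentiometry_csv(series, file.path(out_dir, "potentiometry.csv"))
  truth$potentiometry <- list(e_enz_mV = -138, e_dye_mV = -125,
                              n_f = 2, n_d = 2, f_tot_uM = eq_truth$f_tot,
                              d_tot_uM = eq_truth$d_tot)

  mm <- gen_rates_mm(km = 22, kcat = 258, cfg = cfg(3L))
  write_rates_csv(mm, file.path(out_dir, "rates_mm.csv"))
  truth$mm <- list(km_uM = 22, kcat_s = 258,
                   enzyme_total_uM = attr(mm, "enzyme_total"))

  pp <- gen_rates_pingpong(kcat = 50, ka = 33, kb = 111, cfg = cfg(4L))
  write_rates_csv(pp, file.path(out_dir, "rates_pingpong.csv"))
  truth$pingpong <- list(kcat_s = 50, ka_uM = 33, kb_uM = 111,
                         enzyme_total_uM = attr(pp, "enzyme_total"))

  nadh <- c(1, 2, 5, 10, 20, 50, 200, 1000, 5000)
  k_true <- 147 * nadh / (6.4 + nadh)
  tr_dir <- file.path(out_dir, "traces")
  dir.create(tr_dir, showWarnings = FALSE)
  mf <- data.frame(file = sprintf("trace_%02d.csv", seq_along(nadh)),
                   nadh_uM = nadh)
  for (i in seq_along(nadh)) {
    tr <- gen_trace(kobs = k_true[i], cfg = cfg(10L + i), nadh = nadh[i])
    write_trace_csv(tr, file.path(tr_dir, mf$file[i]))
  }
  utils::write.csv(mf, file.path(tr_dir, "manifest.csv"), row.names = FALSE)
  truth$stopflow <- list(k_max_s = 147, k_half_uM = 6.4, nadh_uM = nadh)

  mk <- sec_markers_superose12()
  utils::write.csv(data.frame(name = mk$name, kDa = mk$mass_kda,
                              mL = mk$elution_ml),
                   file.path(out_dir, "sec_markers.csv"), row.names = FALSE)
  truth$sec <- list(monomer_mass_da = 21288, elution_ml = 9.5)

  sx <- gen_saxs_mixture(weights = c(0.09, 0.91),
                         cfg = sim_config(seed = seed + 20L,
                                          noise_rel = max(noise_rel / 2, 0.01)))
  write_saxs_dat(sx$curve, file.path(out_dir, "saxs_curve.dat"))
  comp <- sx$components
  for (nm in colnames(comp$intensities))
    utils::write.table(
      data.frame(q = comp$q, I = comp$intensities[, nm]),
      file.path(out_dir, paste0("ff_", nm, ".dat")),
      row.names = FALSE, col.names = FALSE)
  truth$saxs <- list(weights = c(0.09, 0.91),
                     components = colnames(comp$intensities))

  jsonlite::write_json(truth, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(truth)
}

#' Recompute the package's worked-example quantities
#'
#' Re-derives the headline arithmetic of the FerB characterization from its
#' inputs — the midpoint-potential intercept calculation, the Gibbs energy
#' of FMN binding and the phosphate contribution, the riboflavin fold
#' change, the specific-activity conversion for the EmoB comparison and the
#' specificity constants — and compares each against the published value at
#' its display precision.
#'
#' @return A data frame with columns `check`, `computed`, `printed`, `pass`.
#' @examples
#' paper_checks()
#' @export
paper_checks <- function() {
  checks <- list(
    list(check = "midpoint potential from intercept (mV)",
         computed = potential_from_intercept(-125, -0.45, 2),
         printed = -138, digits = 0),
    list(check = "Gibbs energy of FMN binding (kJ/mol)",
         computed = gibbs_from_kd(27e-9)$dg_b,
         printed = -43.2, digits = 1),
    list(check = "phosphate contribution to binding (kJ/mol)",
         computed = delta_delta_g(gibbs_from_kd(6.58e-6),
                                  gibbs_from_kd(27e-9)),
         printed = 13.6, digits = 1),
    list(check = "riboflavin/FMN Kd fold change",
         computed = fold_change(6.58e-6, 27e-9),
         printed = 244, digits = 0),
    # reported as an integer rounded from the one-decimal intermediate 396.5
    list(check = "kcat from specific activity (s^-1)",
         computed = kcat_from_specific_activity(1111, 21412),
         printed = 397, digits = c(1, 0)),
    list(check = "specificity, wild type (mM^-1 s^-1)",
         computed = specificity(22, 258),
         printed = 11727, digits = 0),
    list(check = "specificity, Y78A (mM^-1 s^-1)",
         computed = specificity(40, 196),
         printed = 4900, digits = 0))
  out <- do.call(rbind, lapply(checks, function(ck) {
    displayed <- Reduce(function(v, d) display_round(v, d), ck$digits,
                        ck$computed)
    data.frame(check = ck$check, computed = ck$computed,
               printed = ck$printed, pass = displayed == ck$printed)
  }))
  rownames(out) <- NULL
  out
}

#' Display rounding (half away from zero)
#'
#' Rounds the way printed values in reports are rounded: ties go away from
#' zero, unlike [round()]'s round-half-even. Staged rounding through an
#' intermediate precision (e.g. 396.48 -> 396.5 -> 397) reproduces
#' hand-reported figures.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded values.
#' @export
display_round <- function(x, digits = 0) {
  f <- 10^digits
  sign(x) * floor(abs(x) * f + 0.5) / f
}
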