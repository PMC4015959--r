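#' Read a titration CSV
#'
#' Expects a header row and columns `protein_uM, emission`, optionally
#' `dilution_factor`.
#'
#' @param path CSV file path.
#' @param flavin_total_nM Total flavin, nM.
#' @param temperature_K Temperature, K.
#' @return A [titration_curve()].
#' @export
read_titration_csv <- function(path, flavin_total_nM = 100,
                               temperature_K = 298.15) {
  df <- utils::read.csv(path)
  if (!all(c("protein_uM", "emission") %in% names(df)))
    stop("titration CSV needs columns protein_uM, emission")
  titration_curve(df$protein_uM, df$emission,
                  flavin_total = flavin_total_nM,
                  temperature = temperature_K,
                  dilution_factor = df$dilution_factor)
}

#' Write a titration CSV
#' @param curve A [titration_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_titration_csv <- function(curve, path) {
  utils::write.csv(as.data.frame(curve), path, row.names = FALSE)
  invisible(path)
}

#' Read a potentiometry time series CSV
#'
#' Columns `t_min, A_450, A_dye`; totals and optics come from arguments
#' (typically a key-value sidecar or CLI flags).
#'
#' @param path CSV file path.
#' @param f_tot,d_tot Total flavin and dye concentrations, µM.
#' @param path_length Optical path, cm.
#' @param dye_wavelength Dye analysis wavelength, nm (610 for indigo
#'   carmine, 521 for phenosafranin).
#' @return An [absorbance_series()].
#' @export
read_potentiometry_csv <- function(path, f_tot, d_tot, path_length = 1,
                                   dye_wavelength = 610) {
  df <- utils::read.csv(path)
  if (!all(c("t_min", "A_450", "A_dye") %in% names(df)))
    stop("potentiometry CSV needs columns t_min, A_450, A_dye")
  absorbance_series(df$t_min, cbind(df$A_450, df$A_dye),
                    f_tot = f_tot, d_tot = d_tot, path_length = path_length,
                    wavelengths = c(450, dye_wavelength))
}

#' Write a potentiometry time series CSV
#' @param series An [absorbance_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_potentiometry_csv <- function(series, path) {
  utils::write.csv(data.frame(t_min = series$times,
                              A_450 = series$absorbance[, 1],
                              A_dye = series$absorbance[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a single-substrate initial-rate CSV
#'
#' Columns `S_uM, v_uM_per_s`.
#'
#' @param path CSV file path.
#' @param enzyme_total Enzyme concentration, µM.
#' @param acceptor,acceptor_conc Fixed co-substrate name and concentration (µM).
#' @return A [rate_dataset()].
#' @export
read_rates_csv <- function(path, enzyme_total, acceptor = "UQ-0",
                           acceptor_conc = 100) {
  df <- utils::read.csv(path)
  if (!all(c("S_uM", "v_uM_per_s") %in% names(df)))
    stop("rate CSV needs columns S_uM, v_uM_per_s")
  rate_dataset(df$S_uM, df$v_uM_per_s, enzyme_total = enzyme_total,
               acceptor = acceptor, acceptor_conc = acceptor_conc)
}

#' Read a bisubstrate initial-rate CSV
#'
#' Columns `A_uM, B_uM, v_uM_per_s`.
#'
#' @param path CSV file path.
#' @param enzyme_total Enzyme concentration, µM.
#' @return A [pingpong_dataset()].
#' @export
read_pingpong_csv <- function(path, enzyme_total) {
  df <- utils::read.csv(path)
  if (!all(c("A_uM", "B_uM", "v_uM_per_s") %in% names(df)))
    stop("bisubstrate CSV needs columns A_uM, B_uM, v_uM_per_s")
  pingpong_dataset(df$A_uM, df$B_uM, df$v_uM_per_s,
                   enzyme_total = enzyme_total)
}

#' Write a rate dataset CSV
#' @param data A [rate_dataset()] or [pingpong_dataset()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rates_csv <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' Read a stopped-flow trace CSV
#'
#' Columns `t_s, A450`.
#'
#' @param path CSV file path.
#' @param nadh Post-mix NADH concentration, µM (metadata).
#' @param temperature Temperature, °C.
#' @return A [stopped_flow_trace()].
#' @export
read_trace_csv <- function(path, nadh = NA_real_, temperature = 10) {
  df <- utils::read.csv(path)
  if (!all(c("t_s", "A450") %in% names(df)))
    stop("trace CSV needs columns t_s, A450")
  stopped_flow_trace(df$t_s, df$A450, nadh = nadh, temperature = temperature)
}

#' Write a stopped-flow trace CSV
#' @param trace A [stopped_flow_trace()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace), path, row.names = FALSE)
  invisible(path)
}

#' Read a SEC marker CSV
#'
#' Columns `name, kDa, mL`.
#'
#' @param path CSV file path.
#' @return A [sec_marker_table()].
#' @export
read_markers_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("name", "kDa", "mL") %in% names(df)))
    stop("marker CSV needs columns name, kDa, mL")
  sec_marker_table(df$name, df$kDa, df$mL)
}

#' Read a three-column SAXS curve
#'
#' Standard whitespace-separated `.dat` layout (q, I, sigma) with `#`
#' comment lines.
#'
#' @param path File path.
#' @return A [scattering_curve()].
#' @export
read_saxs_dat <- function(path) {
  df <- utils::read.table(path, comment.char = "#",
                          col.names = c("q", "I", "sigma"))
  scattering_curve(df$q, df$I, df$sigma)
}

#' Write a three-column SAXS curve
#' @param curve A [scattering_curve()].
#' @param path Output path.
#' @param header Comment line written at the top.
#' @return `path`, invisibly.
#' @export
write_saxs_dat <- function(curve, path, header = "q I sigma") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#", header), con)
  utils::write.table(as.data.frame(curve), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read component form factors from .dat files
#'
#' Each file holds `q I` (a third sigma column is ignored); all files must
#' share the q grid.
#'
#' @param paths Character vector of file paths; names become component names.
#' @return A [form_factor_set()].
#' @export
read_form_factors <- function(paths) {
  nms <- names(paths) %||% tools::file_path_sans_ext(basename(paths))
  tabs <- lapply(paths, function(p)
    utils::read.table(p, comment.char = "#"))
  q <- tabs[[1]][, 1]
  for (tb in tabs[-1])
    if (nrow(tb) != length(q) || any(abs(tb[, 1] - q) > 1e-10))
      stop("form-factor files must share a common q grid")
  mat <- vapply(tabs, function(tb) tb[, 2], numeric(length(q)))
  colnames(mat) <- nms
  form_factor_set(q, mat)
}
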