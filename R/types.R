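#' Fluorescence-quenching titration curve
#'
#' A titration of apoprotein into a fixed total concentration of free flavin,
#' followed by the flavin emission (excitation 450 nm, emission 519 nm).
#' Binding quenches the fluorescence, so emission falls as protein is added.
#'
#' @param protein_total Titrant (apoprotein) total concentrations, µM.
#' @param emission Emission intensities, arbitrary units.
#' @param flavin_total Total flavin concentration, nM (fixed across the
#'   series; 100 nM in the standard assay).
#' @param temperature Temperature, K. Default 298.15 (25 °C).
#' @param dilution_factor Optional per-point dilution factors applied to
#'   `flavin_total` (1 = no dilution).
#'
#' @return An object of class `titration_curve` (a data frame with
#'   attributes `flavin_total` and `temperature`).
#' @export
titration_curve <- function(protein_total, emission, flavin_total = 100,
                            temperature = 298.15, dilution_factor = NULL) {
  protein_total <- as.numeric(protein_total)
  emission <- as.numeric(emission)
  if (length(protein_total) != length(emission))
    stop("`protein_total` and `emission` must have equal length")
  if (length(protein_total) < 4L)
    stop("a titration needs at least 4 points")
  if (any(protein_total < 0)) stop("negative titrant concentrations")
  if (any(!is.finite(emission))) stop("non-finite emission values")
  if (!is.null(dilution_factor)) {
    dilution_factor <- as.numeric(dilution_factor)
    if (length(dilution_factor) != length(emission) ||
        any(dilution_factor <= 0))
      stop("`dilution_factor` must be positive and match the series length")
  }
  if (flavin_total <= 0) stop("`flavin_total` must be > 0")
  if (is.unsorted(protein_total))
    warning("titrant series is not non-decreasing")
  df <- data.frame(protein_uM = protein_total, emission = emission)
  if (!is.null(dilution_factor)) df$dilution_factor <- dilution_factor
  structure(df,
            flavin_total = flavin_total, temperature = temperature,
            class = c("titration_curve", "data.frame"))
}

#' @export
print.titration_curve <- function(x, ...) {
  cat(sprintf("<titration_curve> %d points, flavin %.3g nM, T = %.2f K\n",
              nrow(x), attr(x, "flavin_total"), attr(x, "temperature")))
  print.data.frame(x, ...)
  invisible(x)
}

#' Species-by-wavelength extinction coefficient matrix
#'
#' Millimolar extinction coefficients of the four redox species followed in a
#' dye-coupled equilibration experiment, at the analysis wavelengths (450 nm
#' for the flavin plus the dye band, 610 nm for indigo carmine or 521 nm for
#' phenosafranin). Reduced flavin (hydroquinone) and leuco-dyes absorb weakly
#' at these wavelengths, so their coefficients default to zero.
#'
#' @param eps Numeric 4 x W matrix (mM^-1 cm^-1) with rownames
#'   `flavin_ox`, `flavin_red`, `dye_ox`, `dye_red`.
#' @param wavelengths Wavelengths, nm; one per column of `eps`.
#'
#' @return An `extinction_matrix`.
#' @examples
#' extinction_matrix()  # default flavin/indigo-carmine pair at 450 and 610 nm
#' @export
extinction_matrix <- function(eps = NULL, wavelengths = c(450, 610)) {
  species <- c("flavin_ox", "flavin_red", "dye_ox", "dye_red")
  if (is.null(eps)) {
    # flavin_ox: 12.5 at 450 (oxidized isoalloxazine band), small 610 tail;
    # indigo carmine ox: strong 610 band with a minor 450 contribution
    eps <- rbind(flavin_ox = c(12.5, 0.3),
                 flavin_red = c(0, 0),
                 dye_ox = c(1.8, 20.0),
                 dye_red = c(0, 0))
  }
  eps <- as.matrix(eps)
  if (nrow(eps) != 4L || is.null(rownames(eps)) ||
      !setequal(rownames(eps), species))
    stop("`eps` must be a 4-row matrix with rownames flavin_ox, flavin_red, ",
         "dye_ox, dye_red")
  eps <- eps[species, , drop = FALSE]
  if (ncol(eps) != length(wavelengths))
    stop("one column of `eps` per wavelength")
  if (any(eps < 0)) stop("extinction coefficients must be >= 0")
  colnames(eps) <- paste0("A_", wavelengths)
  structure(list(eps = eps, wavelengths = as.numeric(wavelengths),
                 species = species),
            class = "extinction_matrix")
}

#' @export
print.extinction_matrix <- function(x, ...) {
  cat("<extinction_matrix> (mM^-1 cm^-1), wavelengths:",
      paste(x$wavelengths, collapse = ", "), "nm\n")
  print(x$eps)
  invisible(x)
}

#' Two-wavelength absorbance time series from a reductive equilibration
#'
#' @param times Times, minutes, increasing from 0.
#' @param absorbance Matrix (time x wavelength) of absorbances.
#' @param f_tot,d_tot Total flavin and dye concentrations, µM.
#' @param path_length Optical path, cm.
#' @param wavelengths Wavelengths, nm, matching the absorbance columns.
#'
#' @return An `absorbance_series`.
#' @export
absorbance_series <- function(times, absorbance, f_tot, d_tot,
                              path_length = 1, wavelengths = c(450, 610)) {
  times <- as.numeric(times)
  absorbance <- as.matrix(absorbance)
  if (is.unsorted(times, strictly = TRUE))
    stop("`times` must be strictly increasing")
  if (nrow(absorbance) != length(times))
    stop("one absorbance row per time point")
  if (ncol(absorbance) != length(wavelengths))
    stop("one absorbance column per wavelength")
  if (f_tot <= 0 || d_tot <= 0) stop("totals must be > 0")
  if (path_length <= 0) stop("`path_length` must be > 0")
  colnames(absorbance) <- paste0("A_", wavelengths)
  structure(list(times = times, absorbance = absorbance,
                 f_tot = f_tot, d_tot = d_tot,
                 path_length = path_length,
                 wavelengths = as.numeric(wavelengths)),
            class = "absorbance_series")
}

#' @export
print.absorbance_series <- function(x, ...) {
  cat(sprintf(
    "<absorbance_series> %d times (0-%.3g min), F_tot %.3g uM, D_tot %.3g uM\n",
    length(x$times), max(x$times), x$f_tot, x$d_tot))
  invisible(x)
}

#' Initial-rate dataset for a single varied substrate
#'
#' @param substrate Substrate concentrations, µM.
#' @param velocity Initial velocities, µM s^-1.
#' @param enzyme_total Total enzyme concentration, µM.
#' @param acceptor Name of the fixed co-substrate (electron acceptor).
#' @param acceptor_conc Its fixed concentration, µM.
#'
#' @return A `rate_dataset` (data frame with attributes).
#' @export
rate_dataset <- function(substrate, velocity, enzyme_total,
                         acceptor = "UQ-0", acceptor_conc = 100) {
  substrate <- as.numeric(substrate)
  velocity <- as.numeric(velocity)
  if (length(substrate) != length(velocity))
    stop("`substrate` and `velocity` must have equal length")
  if (length(substrate) < 5L) stop("need at least 5 rate measurements")
  if (anyDuplicated(substrate)) stop("substrate concentrations must be distinct")
  if (any(substrate < 0)) stop("negative substrate concentrations")
  if (enzyme_total <= 0) stop("`enzyme_total` must be > 0")
  structure(data.frame(S_uM = substrate, v_uM_per_s = velocity),
            enzyme_total = enzyme_total, acceptor = acceptor,
            acceptor_conc = acceptor_conc,
            class = c("rate_dataset", "data.frame"))
}

#' Initial-rate dataset for two varied substrates (bisubstrate analysis)
#'
#' @param a,b Concentrations of the varied substrates (A = NADH, B = flavin), µM.
#' @param velocity Initial velocities, µM s^-1.
#' @param enzyme_total Total enzyme concentration, µM.
#'
#' @return A `pingpong_dataset` (data frame with attribute `enzyme_total`).
#' @export
pingpong_dataset <- function(a, b, velocity, enzyme_total) {
  a <- as.numeric(a); b <- as.numeric(b); velocity <- as.numeric(velocity)
  if (length(a) != length(b) || length(a) != length(velocity))
    stop("`a`, `b` and `velocity` must have equal length")
  if (any(a <= 0) || any(b <= 0)) stop("substrate concentrations must be > 0")
  if (enzyme_total <= 0) stop("`enzyme_total` must be > 0")
  if (length(unique(b)) < 3L) stop("need at least 3 levels of the fixed substrate")
  structure(data.frame(A_uM = a, B_uM = b, v_uM_per_s = velocity),
            enzyme_total = enzyme_total,
            class = c("pingpong_dataset", "data.frame"))
}

#' Stopped-flow absorbance trace
#'
#' @param t Times after the instrument dead time, s, increasing.
#' @param a450 Absorbance at 450 nm.
#' @param nadh Post-mix NADH concentration, µM (optional, for batch analysis).
#' @param temperature Temperature, °C.
#'
#' @return A `stopped_flow_trace`.
#' @export
stopped_flow_trace <- function(t, a450, nadh = NA_real_, temperature = 10) {
  t <- as.numeric(t); a450 <- as.numeric(a450)
  if (length(t) != length(a450)) stop("`t` and `a450` must have equal length")
  if (length(t) < 20L) stop("a trace needs at least 20 points")
  if (any(t < 0) || is.unsorted(t, strictly = TRUE))
    stop("`t` must be non-negative and strictly increasing")
  structure(data.frame(t_s = t, A450 = a450),
            nadh = nadh, temperature = temperature,
            class = c("stopped_flow_trace", "data.frame"))
}

#' Small-angle X-ray scattering curve
#'
#' @param q Scattering vector, Å^-1, increasing and positive.
#' @param intensity Intensities, arbitrary units.
#' @param sigma Per-point standard uncertainties (> 0).
#'
#' @return A `scattering_curve`.
#' @export
scattering_curve <- function(q, intensity, sigma) {
  q <- as.numeric(q); intensity <- as.numeric(intensity)
  sigma <- as.numeric(sigma)
  if (length(q) != length(intensity) || length(q) != length(sigma))
    stop("`q`, `intensity` and `sigma` must have equal length")
  if (any(q <= 0) || is.unsorted(q, strictly = TRUE))
    stop("`q` must be positive and strictly increasing")
  if (any(sigma <= 0)) stop("`sigma` must be > 0")
  structure(data.frame(q = q, I = intensity, sigma = sigma),
            class = c("scattering_curve", "data.frame"))
}

#' Set of component form factors on a common q grid
#'
#' @param q Scattering vector grid, Å^-1.
#' @param intensities Matrix (length(q) x K) of component intensities; column
#'   names identify the components (e.g. `dimer`, `tetramer`).
#'
#' @return A `form_factor_set`.
#' @export
form_factor_set <- function(q, intensities) {
  q <- as.numeric(q)
  intensities <- as.matrix(intensities)
  if (nrow(intensities) != length(q))
    stop("one intensity row per q value")
  if (is.null(colnames(intensities)))
    colnames(intensities) <- paste0("component", seq_len(ncol(intensities)))
  if (any(intensities < 0)) stop("form-factor intensities must be >= 0")
  structure(list(q = q, intensities = intensities),
            class = "form_factor_set")
}

#' Size-exclusion chromatography marker table
#'
#' @param name Marker protein names.
#' @param mass_kda Molecular masses, kDa.
#' @param elution_ml Elution volumes, mL.
#'
#' @return A `sec_marker_table`.
#' @examples
#' sec_markers_superose12()
#' @export
sec_marker_table <- function(name, mass_kda, elution_ml) {
  mass_kda <- as.numeric(mass_kda); elution_ml <- as.numeric(elution_ml)
  if (length(name) != length(mass_kda) || length(name) != length(elution_ml))
    stop("marker columns must have equal length")
  if (length(name) < 3L) stop("need at least 3 markers")
  if (any(mass_kda <= 0) || any(elution_ml <= 0))
    stop("masses and volumes must be positive")
  ord <- order(elution_ml)
  if (is.unsorted(rev(log10(mass_kda[ord]))))
    warning("log-mass is not monotone decreasing in elution volume")
  structure(data.frame(name = as.character(name), mass_kda = mass_kda,
                       elution_ml = elution_ml),
            class = c("sec_marker_table", "data.frame"))
}

#' Standard marker set for an analytical Superose 12 column
#'
#' Albumin (67 kDa), ovalbumin (43 kDa), chymotrypsinogen A (25 kDa) and
#' ribonuclease A (13.7 kDa), with nominal elution volumes from a linear
#' log-mass calibration chosen so that a 40 kDa dimer elutes near 9.5 mL.
#'
#' @return A `sec_marker_table`.
#' @export
sec_markers_superose12 <- function() {
  masses <- c(albumin = 67, ovalbumin = 43, chymotrypsinogen_A = 25,
              ribonuclease_A = 13.7)
  # nominal line: log10(kDa) = 4.30 - 0.284 * Ve  (Ve in mL)
  ve <- (4.30 - log10(masses)) / 0.284
  sec_marker_table(names(masses), masses, round(ve, 2))
}
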