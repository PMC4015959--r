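#' Published kinetic and redox parameters of the FerB variant panel
#'
#' Steady-state NADH-oxidation parameters (fixed 0.1 mM UQ-0 acceptor),
#' midpoint potentials and stopped-flow rate constants for wild-type
#' FerBHis6 and its active-site mutants, as printed: each value with its
#' standard error, `NA` where not determined. Used for internal-consistency
#' checks of the specificity column and by the worked-example mode.
#'
#' @return A data frame with columns `variant`, `km`, `km_se` (µM), `kcat`,
#'   `kcat_se` (s^-1), `spec`, `spec_se` (mM^-1 s^-1), `e_m`, `e_m_se`
#'   (mV), `kobs`, `kobs_se` (s^-1).
#' @export
ferb_variant_table <- function() {
  tab <- rbind(
    c("WT",    22,   2,   258,    6,    11727, 1100, -138,  2, 147.01, 0.35),
    c("E77A",  180,  30,  17.9,   3.0,  99,    23,   -225, 10, NA,     NA),
    c("E77K",  30,   8,   0.75,   0.05, 25,    7,    -239,  7, 0.228,  0.001),
    c("E77L",  250,  30,  0.072,  0.006, 0.29, 0.04, -229,  8, NA,     NA),
    c("E77M",  420,  160, 2.5,    1.0,  6.0,   3.3,  -223,  4, NA,     NA),
    c("Y78A",  40,   10,  196,    13,   4900,  1267, NA,   NA, NA,     NA),
    c("R80E",  30,   3,   0.275,  0.006, 9.2,  0.9,  -230,  7, 0.608,  0.003),
    c("R80K",  350,  80,  9.5,    1.4,  27,    7,    -148,  2, NA,     NA),
    c("R80M",  780,  280, 0.302,  0.084, 0.39, 0.18, -148,  6, NA,     NA),
    c("R80L",  580,  150, 0.142,  0.030, 0.24, 0.08, NA,   NA, NA,     NA),
    c("R95A",  20,   2,   146,    4,    7292,  756,  -217, 11, NA,     NA),
    c("R95E",  70,   9,   21.1,   0.9,  302,   41,   -245,  1, 45.15,  0.09),
    c("S113A", 60,   20,  76.7,   7.2,  1278,  443,  -239,  1, 27.88,  0.03),
    c("G115F", 410,  90,  2.2,    0.3,  5.4,   1.4,  NA,   NA, 2.607,  0.007),
    c("G115I", 630,  70,  1.7,    0.1,  2.7,   0.3,  -149,  3, NA,     NA),
    c("G118F", 85,   6,   77,     9,    906,   124,  NA,   NA, NA,     NA),
    c("G118I", 38,   3,   12,     1,    316,   36,   NA,   NA, NA,     NA))
  out <- data.frame(variant = tab[, 1], apply(tab[, -1], 2, as.numeric))
  names(out) <- c("variant", "km", "km_se", "kcat", "kcat_se",
                  "spec", "spec_se", "e_m", "e_m_se", "kobs", "kobs_se")
  out
}

# Half-ULP of the last printed digit of a number as formatted.
.half_ulp <- function(x) {
  vapply(x, function(xi) {
    s <- format(xi, scientific = FALSE, trim = TRUE)
    dec <- regmatches(s, regexpr("\\.[0-9]+$", s))
    if (length(dec) == 0) 0.5 else 0.5 * 10^-(nchar(dec) - 1L)
  }, numeric(1))
}

#' Internal-consistency check of a printed specificity column
#'
#' For each variant, tests whether the printed k_cat/K_m is consistent with
#' the printed K_m and k_cat once their display rounding is taken into
#' account: the interval of ratios attainable from inputs within half a
#' unit of their last printed digits, widened by one unit in the ratio's
#' own last printed digit, must contain the printed ratio.
#'
#' @param table A data frame with columns `km`, `kcat`, `spec` (defaults to
#'   [ferb_variant_table()]).
#' @return The table with added columns `spec_computed` (ratio of the
#'   printed values, mM^-1 s^-1) and `consistent`.
#' @export
check_specificity_table <- function(table = ferb_variant_table()) {
  km_h <- .half_ulp(table$km)
  kc_h <- .half_ulp(table$kcat)
  sp_u <- 2 * .half_ulp(table$spec)
  lo <- specificity(table$km + km_h, table$kcat - kc_h)
  hi <- specificity(pmax(table$km - km_h, 1e-12), table$kcat + kc_h)
  table$spec_computed <- specificity(table$km, table$kcat)
  table$consistent <- table$spec >= lo - sp_u & table$spec <= hi + sp_u
  table
}
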