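#' Simulation configuration for the synthetic-data generators
#'
#' Every generator in the package takes a `sim_config` controlling the random
#' seed and the noise model. Noise is multiplicative Gaussian on the signal
#' (the dominant error structure of plate readers, diode-array
#' spectrophotometers and stopped-flow detectors), with an optional absolute
#' Gaussian floor added on top.
#'
#' @param seed Integer seed; the same seed and parameters always give
#'   bit-identical output. `NULL` leaves the RNG state alone.
#' @param noise_rel Relative (fractional) standard deviation of the
#'   multiplicative Gaussian noise. `0` gives noiseless curves.
#' @param noise_abs Absolute noise floor, in signal units. Default `0`.
#' @param n_points Default number of points per generated curve (generators
#'   with an explicit design grid ignore this).
#'
#' @return An object of class `sim_config`.
#' @examples
#' cfg <- sim_config(seed = 1, noise_rel = 0.02)
#' @export
sim_config <- function(seed = NULL, noise_rel = 0, noise_abs = 0,
                       n_points = 12L) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("`seed` must be a single integer or NULL")
  }
  stopifnot(is.numeric(noise_rel), length(noise_rel) == 1L, noise_rel >= 0,
            is.numeric(noise_abs), length(noise_abs) == 1L, noise_abs >= 0)
  n_points <- as.integer(n_points)
  if (is.na(n_points) || n_points < 4L)
    stop("`n_points` must be an integer >= 4")
  structure(list(seed = seed, noise_rel = noise_rel, noise_abs = noise_abs,
                 n_points = n_points),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed:", if (is.null(x$seed)) "none" else x$seed,
      " noise_rel:", x$noise_rel,
      " noise_abs:", x$noise_abs,
      " n_points:", x$n_points, "\n")
  invisible(x)
}

# Seed the RNG from a sim_config (no-op for NULL seed).
.seed_rng <- function(cfg) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  invisible(NULL)
}

# Apply the configured noise model to a clean signal vector.
.apply_noise <- function(y, cfg) {
  if (cfg$noise_rel == 0 && cfg$noise_abs == 0) return(y)
  n <- length(y)
  out <- y
  if (cfg$noise_rel > 0) out <- out * (1 + stats::rnorm(n, 0, cfg$noise_rel))
  if (cfg$noise_abs > 0) out <- out + stats::rnorm(n, 0, cfg$noise_abs)
  out
}

.assert_config <- function(cfg) {
  if (!inherits(cfg, "sim_config"))
    stop("`cfg` must be created by sim_config()")
  invisible(cfg)
}
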