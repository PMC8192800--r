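#' Analysis configuration
#'
#' Collects the fixed constants of the analysis in one validated object:
#' the two formant-averaging time windows, the mel-conversion variant, the
#' coverage level of the production ellipse, the MAD screening rule, and the
#' identification-task design.
#'
#' @param initial_window_ms Absolute initial window in ms, length-2 numeric.
#'   Default `c(0, 50)`: the first 50 ms of the vowel.
#' @param midpoint_fraction Relative midpoint window as fractions of token
#'   duration, length-2 numeric. Default `c(0.25, 0.75)`: the middle 50%.
#' @param mel_formula_id `"htk2595"` for m = 2595 log10(1 + f/700) (default)
#'   or `"natural1127"` for m = 1127 ln(1 + f/700).
#' @param ellipse_coverage Coverage of the production ellipse, in (0, 1).
#'   Default 0.95.
#' @param mad_k Multiplier on the MAD for outlier screening. Default 2.
#' @param mad_consistency_constant Scale constant applied to the MAD; 1 =
#'   raw MAD (default), 1.4826 = normal-consistent MAD.
#' @param mad_variables Measure names screened by the MAD filter. Default:
#'   labeling consistency, log contrast distance, log ellipse area (the
#'   centering ratio is checked for normality but not screened).
#' @param n_steps Number of continuum steps. Default 11.
#' @param reps_per_step Presentations per step in the identification task.
#'   Default 20.
#' @param overlap_duration_ms Duration threshold (ms) below which a token is
#'   additionally flagged for reporting; the geometric window-overlap flag is
#'   computed independently. Default 150.
#' @param s_bounds,x0_bounds Box constraints for the psychometric fit, in
#'   continuum steps.
#' @param rng_seed Optional integer seed recorded in run logs.
#'
#' @return An object of class `"vpp_config"` (a validated list).
#' @export
#' @examples
#' cfg <- analysis_config()
#' cfg$ellipse_coverage
analysis_config <- function(initial_window_ms = c(0, 50),
                            midpoint_fraction = c(0.25, 0.75),
                            mel_formula_id = c("htk2595", "natural1127"),
                            ellipse_coverage = 0.95,
                            mad_k = 2,
                            mad_consistency_constant = 1,
                            mad_variables = c("labeling_consistency",
                                              "log_contrast_distance",
                                              "log_ellipse_area"),
                            n_steps = 11L,
                            reps_per_step = 20L,
                            overlap_duration_ms = 150,
                            s_bounds = c(0.01, 50),
                            x0_bounds = c(-5, 17),
                            rng_seed = NULL) {
  mel_formula_id <- match.arg(mel_formula_id)
  stopifnot(length(initial_window_ms) == 2, length(midpoint_fraction) == 2)
  if (initial_window_ms[1] >= initial_window_ms[2])
    vpp_validation_error("initial_window_ms must be a well-ordered interval")
  if (midpoint_fraction[1] >= midpoint_fraction[2] ||
      midpoint_fraction[1] < 0 || midpoint_fraction[2] > 1)
    vpp_validation_error("midpoint_fraction must be well-ordered within [0, 1]")
  if (!is.numeric(ellipse_coverage) || ellipse_coverage <= 0 || ellipse_coverage >= 1)
    vpp_validation_error("ellipse_coverage must lie strictly in (0, 1)")
  if (!is.numeric(mad_k) || mad_k <= 0)
    vpp_validation_error("mad_k must be positive")
  n_steps <- as.integer(n_steps)
  reps_per_step <- as.integer(reps_per_step)
  if (n_steps < 2L) vpp_validation_error("n_steps must be at least 2")
  if (reps_per_step < 1L) vpp_validation_error("reps_per_step must be at least 1")
  structure(list(
    initial_window_ms = as.numeric(initial_window_ms),
    midpoint_fraction = as.numeric(midpoint_fraction),
    mel_formula_id = mel_formula_id,
    ellipse_coverage = ellipse_coverage,
    mad_k = mad_k,
    mad_consistency_constant = mad_consistency_constant,
    mad_variables = mad_variables,
    n_steps = n_steps,
    reps_per_step = reps_per_step,
    overlap_duration_ms = overlap_duration_ms,
    s_bounds = as.numeric(s_bounds),
    x0_bounds = as.numeric(x0_bounds),
    rng_seed = rng_seed
  ), class = "vpp_config")
}

#' @export
print.vpp_config <- function(x, ...) {
  cat("vowelpp analysis configuration\n")
  cat(sprintf("  initial window: %g-%g ms; midpoint: %g-%g of duration\n",
              x$initial_window_ms[1], x$initial_window_ms[2],
              x$midpoint_fraction[1], x$midpoint_fraction[2]))
  cat(sprintf("  mel formula: %s; ellipse coverage: %g\n",
              x$mel_formula_id, x$ellipse_coverage))
  cat(sprintf("  MAD screen: k = %g (constant %g) on %s\n", x$mad_k,
              x$mad_consistency_constant,
              paste(x$mad_variables, collapse = ", ")))
  cat(sprintf("  continuum: %d steps x %d reps\n", x$n_steps, x$reps_per_step))
  invisible(x)
}

#' Read / write a run-level configuration file
#'
#' Configurations are stored as a flat JSON key/value object mirroring the
#' fields of [analysis_config()]. Unknown keys raise a schema error naming
#' the key.
#'
#' @param path File path.
#' @return For `read_config`, a `"vpp_config"`; `write_config` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) vpp_io_error(paste0("config file not found: ", path))
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(analysis_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    vpp_schema_error(paste0("unknown config key: ", paste(bad, collapse = ", ")))
  do.call(analysis_config, raw)
}

#' @rdname read_config
#' @param config A `"vpp_config"` object.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "vpp_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  invisible(path)
}
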