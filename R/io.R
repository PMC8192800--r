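# CSV schemas (column names are part of the public contract):
#
# production (token level): participant_id, vowel, trial_index,
#   f1_init, f2_init, f1_mid, f2_mid, duration_ms, excluded
# production (track level): participant_id, vowel, trial_index,
#   time_ms, f1_hz, f2_hz            (one row per frame; auto-detected)
# identification: participant_id, step, response   (response: head/had)
# measures: participant_id, labeling_consistency, log_contrast_distance,
#   log_ellipse_area, centering_ratio

PRODUCTION_COLS <- c("participant_id", "vowel", "trial_index",
                     "f1_init", "f2_init", "f1_mid", "f2_mid",
                     "duration_ms", "excluded")
TRACK_COLS   <- c("participant_id", "vowel", "trial_index",
                  "time_ms", "f1_hz", "f2_hz")
MEASURE_COLS <- c("participant_id", "labeling_consistency",
                  "log_contrast_distance", "log_ellipse_area",
                  "centering_ratio")
VOWELS <- c("EH", "AE")

check_numeric_col <- function(df, col) {
  v <- df[[col]]
  if (is.character(v) || is.factor(v)) {
    suppress <- suppressWarnings(as.numeric(as.character(v)))
    bad <- which(is.na(suppress) & !is.na(v) & trimws(as.character(v)) != "")
    if (length(bad))
      vpp_parse_error(sprintf("non-numeric value in column '%s' at row %d",
                              col, bad[1]))
    v <- suppress
  }
  if (!is.numeric(v) && !is.logical(v))
    vpp_parse_error(sprintf("column '%s' is not numeric", col))
  as.numeric(v)
}

validate_production <- function(df, allow_na_excluded = FALSE) {
  miss <- setdiff(PRODUCTION_COLS, names(df))
  if (length(miss))
    vpp_schema_error(paste0("production table missing column(s): ",
                            paste(miss, collapse = ", ")))
  df$vowel <- toupper(as.character(df$vowel))
  bad_v <- which(!df$vowel %in% VOWELS)
  if (length(bad_v))
    vpp_validation_error(sprintf(
      "row %d: vowel '%s' is not one of %s", bad_v[1], df$vowel[bad_v[1]],
      paste(VOWELS, collapse = "/")))
  for (col in c("f1_init", "f2_init", "f1_mid", "f2_mid", "duration_ms"))
    df[[col]] <- check_numeric_col(df, col)
  df$trial_index <- as.integer(check_numeric_col(df, "trial_index"))
  df$excluded <- as.logical(df$excluded)
  if (any(is.na(df$excluded)))
    vpp_validation_error("column 'excluded' must be logical (true/false)")
  if (any(df$trial_index < 1L, na.rm = TRUE))
    vpp_validation_error("trial_index must be a positive integer")
  fcols <- c("f1_init", "f2_init", "f1_mid", "f2_mid")
  ok_rows <- if (allow_na_excluded) !df$excluded else rep(TRUE, nrow(df))
  fv <- as.matrix(df[ok_rows, fcols, drop = FALSE])
  if (nrow(fv) && (any(is.na(fv)) || any(fv <= 0)))
    vpp_validation_error("formant values must be strictly positive")
  if (any(df$duration_ms < 0, na.rm = TRUE))
    vpp_validation_error("duration_ms must be nonnegative")
  key <- paste(df$participant_id, df$vowel, df$trial_index)
  if (anyDuplicated(key))
    vpp_validation_error(paste0("duplicate (participant, vowel, trial) key: ",
                                key[duplicated(key)][1]))
  df$participant_id <- as.character(df$participant_id)
  df
}

#' Read a production table
#'
#' Accepts either of two CSV schemas and returns a validated token table.
#' A token-level file carries window-averaged mel formant values directly;
#' a track-level file carries one row per analysis frame in Hz and is reduced
#' through [tracks_to_tokens()]. The level is auto-detected from the header.
#' Rows flagged `excluded = TRUE` (formant-tracking failures) are retained
#' with their flag so exclusion counts stay reportable.
#'
#' @param path CSV file path with a header row.
#' @param config An [analysis_config()]; used for windowing and mel
#'   conversion when the input is track-level.
#' @return A data frame with columns `participant_id, vowel, trial_index,
#'   f1_init, f2_init, f1_mid, f2_mid` (mel), `duration_ms, excluded`.
#' @export
read_production_table <- function(path, config = analysis_config()) {
  if (!file.exists(path)) vpp_io_error(paste0("file not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (all(TRACK_COLS %in% names(df)))
    return(tracks_to_tokens(df, config))
  validate_production(df)
}

#' Read an identification table
#'
#' One row per two-alternative forced-choice trial: `participant_id`, the
#' continuum `step` (1-based index), and the `response` word (`"head"` or
#' `"had"`, case-insensitive).
#'
#' @inheritParams read_production_table
#' @return A data frame `participant_id, step, response` with `response`
#'   a factor with levels `HEAD, HAD`.
#' @export
read_identification_table <- function(path, config = analysis_config()) {
  if (!file.exists(path)) vpp_io_error(paste0("file not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("participant_id", "step", "response"), names(df))
  if (length(miss))
    vpp_schema_error(paste0("identification table missing column(s): ",
                            paste(miss, collapse = ", ")))
  validate_identification(df, config)
}

validate_identification <- function(df, config = analysis_config()) {
  df$step <- as.integer(check_numeric_col(df, "step"))
  bad <- which(is.na(df$step) | df$step < 1L | df$step > config$n_steps)
  if (length(bad))
    vpp_range_error(sprintf("row %d: step %s outside [1, %d]",
                            bad[1], df$step[bad[1]], config$n_steps))
  resp <- toupper(trimws(as.character(df$response)))
  bad <- which(!resp %in% c("HEAD", "HAD"))
  if (length(bad))
    vpp_parse_error(sprintf("row %d: response '%s' is not head/had",
                            bad[1], df$response[bad[1]]))
  df$response <- factor(resp, levels = c("HEAD", "HAD"))
  df$participant_id <- as.character(df$participant_id)
  df
}

validate_measures <- function(df) {
  miss <- setdiff(MEASURE_COLS, names(df))
  if (length(miss))
    vpp_schema_error(paste0("measures table missing column(s): ",
                            paste(miss, collapse = ", ")))
  if (anyDuplicated(df$participant_id))
    vpp_validation_error("participant ids must be unique")
  num <- as.matrix(df[, setdiff(MEASURE_COLS, "participant_id")])
  if (any(!is.finite(num)))
    vpp_validation_error("measure values must be finite")
  if (any(df$labeling_consistency < 0))
    vpp_validation_error("labeling_consistency must be nonnegative")
  if (any(df$centering_ratio > 1))
    vpp_validation_error("centering_ratio cannot exceed 1")
  df$participant_id <- as.character(df$participant_id)
  df
}

#' Write / read a per-participant measures table
#'
#' `write_measures_table` validates and writes the four per-participant
#' measures as CSV at full precision; `read_measures_table` reads it back so
#' that the round trip is lossless.
#'
#' @param measures Non-empty data frame with columns `participant_id,
#'   labeling_consistency, log_contrast_distance, log_ellipse_area,
#'   centering_ratio`.
#' @param path CSV file path.
#' @return `write_measures_table` returns `path` invisibly;
#'   `read_measures_table` returns the validated data frame.
#' @export
write_measures_table <- function(measures, path) {
  if (!is.data.frame(measures) || nrow(measures) == 0L)
    vpp_precondition_error("measures table must be non-empty")
  measures <- validate_measures(measures)
  ok <- tryCatch({
    write.csv(format(measures[, MEASURE_COLS], digits = 17, trim = TRUE),
              path, row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) vpp_io_error(paste0("cannot write measures table to: ", path))
  invisible(path)
}

#' @rdname write_measures_table
#' @export
read_measures_table <- function(path) {
  if (!file.exists(path)) vpp_io_error(paste0("file not found: ", path))
  df <- read.csv(path, stringsAsFactors = FALSE)
  for (col in setdiff(MEASURE_COLS, "participant_id"))
    if (col %in% names(df)) df[[col]] <- check_numeric_col(df, col)
  validate_measures(df)
}
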