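#' Convert frequency from Hz to the mel scale
#'
#' Two common variants of the same family are supported:
#' `"htk2595"` gives m = 2595 log10(1 + f/700); `"natural1127"` gives
#' m = 1127 ln(1 + f/700). Both are strictly increasing, continuous, and map
#' 0 Hz to 0 mel; they differ only by a constant factor (1127 vs
#' 2595/ln(10) ~ 1127.01).
#'
#' @param f Frequency in Hz, numeric vector, all values >= 0.
#' @param formula Which variant to use; default `"htk2595"`.
#' @return Frequency in mel, same length as `f`.
#' @export
#' @examples
#' hz_to_mel(700)   # 2595 * log10(2) ~ 781.17
#' hz_to_mel(1000)  # ~ 1000.1
hz_to_mel <- function(f, formula = c("htk2595", "natural1127")) {
  formula <- match.arg(formula)
  if (!is.numeric(f)) vpp_domain_error("frequency must be numeric")
  if (any(!is.finite(f)) || any(f < 0))
    vpp_domain_error("frequency must be finite and nonnegative")
  switch(formula,
         htk2595     = 2595 * log10(1 + f / 700),
         natural1127 = 1127 * log(1 + f / 700))
}

#' Inverse of [hz_to_mel()]
#' @param m Frequency in mel, numeric vector, all values >= 0.
#' @inheritParams hz_to_mel
#' @return Frequency in Hz.
#' @export
mel_to_hz <- function(m, formula = c("htk2595", "natural1127")) {
  formula <- match.arg(formula)
  if (any(!is.finite(m)) || any(m < 0))
    vpp_domain_error("mel frequency must be finite and nonnegative")
  switch(formula,
         htk2595     = 700 * (10^(m / 2595) - 1),
         natural1127 = 700 * (exp(m / 1127) - 1))
}

# The two averaging windows for a token of duration d (ms):
#   initial  — absolute [0, 50] ms
#   midpoint — relative [0.25 d, 0.75 d] (the middle 50%)
# Membership is closed at both ends.
window_bounds <- function(duration_ms, config) {
  list(initial  = config$initial_window_ms,
       midpoint = config$midpoint_fraction * duration_ms)
}

#' Average a formant track within the two analysis windows
#'
#' Reduces a per-frame (F1, F2) track in Hz to the four per-token values the
#' production measures use: mean mel-converted F1 and F2 over the initial
#' window and over the midpoint window. Frames are included when their time
#' falls inside the window, boundaries included.
#'
#' @param frame_times_ms Strictly increasing frame times in ms.
#' @param f1_hz,f2_hz Per-frame formant estimates in Hz, same length.
#' @param duration_ms Token duration in ms; defaults to the last frame time.
#' @param config An [analysis_config()].
#' @return Named numeric vector `f1_init, f2_init, f1_mid, f2_mid` in mel.
#' @export
window_average <- function(frame_times_ms, f1_hz, f2_hz,
                           duration_ms = max(frame_times_ms),
                           config = analysis_config()) {
  n <- length(frame_times_ms)
  if (n == 0L) vpp_precondition_error("track has no frames")
  if (length(f1_hz) != n || length(f2_hz) != n)
    vpp_validation_error("track time and formant sequences differ in length")
  if (n > 1L && any(diff(frame_times_ms) <= 0))
    vpp_validation_error("frame times must be strictly increasing")
  if (duration_ms <= 0) vpp_domain_error("duration must be positive")
  wb <- window_bounds(duration_ms, config)
  in_win <- function(b) frame_times_ms >= b[1] & frame_times_ms <= b[2]
  ii <- in_win(wb$initial); im <- in_win(wb$midpoint)
  if (!any(ii)) vpp_precondition_error("no frames inside the initial window")
  if (!any(im)) vpp_precondition_error("no frames inside the midpoint window")
  mel1 <- hz_to_mel(f1_hz, config$mel_formula_id)
  mel2 <- hz_to_mel(f2_hz, config$mel_formula_id)
  c(f1_init = mean(mel1[ii]), f2_init = mean(mel2[ii]),
    f1_mid  = mean(mel1[im]), f2_mid  = mean(mel2[im]))
}

#' Flag geometric overlap of the two analysis windows
#'
#' For short tokens the midpoint window can begin before the initial window
#' ends: its start (0.25 d) precedes 50 ms whenever d < 200 ms. The flag is
#' informational — overlapping tokens are retained in all analyses.
#'
#' @param duration_ms Token duration(s) in ms, positive.
#' @param config An [analysis_config()].
#' @return Logical: `TRUE` where the midpoint window starts strictly before
#'   the initial window ends.
#' @export
#' @examples
#' flag_window_overlap(c(237, 199, 200))  # FALSE TRUE FALSE
flag_window_overlap <- function(duration_ms, config = analysis_config()) {
  if (any(!is.finite(duration_ms)) || any(duration_ms <= 0))
    vpp_domain_error("duration must be positive and finite")
  config$midpoint_fraction[1] * duration_ms < config$initial_window_ms[2]
}

#' Reduce a long-format track table to a window-averaged token table
#'
#' Input is one row per frame with columns `participant_id, vowel,
#' trial_index, time_ms, f1_hz, f2_hz`. Tokens whose track leaves either
#' window empty are retained with `excluded = TRUE` (mirroring
#' tracking-failure bookkeeping) and `NA` formant values.
#'
#' @param tracks Data frame of frames as above.
#' @param config An [analysis_config()].
#' @return A production token data frame (see [read_production_table()]).
#' @export
tracks_to_tokens <- function(tracks, config = analysis_config()) {
  need <- c("participant_id", "vowel", "trial_index", "time_ms", "f1_hz", "f2_hz")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    vpp_schema_error(paste0("track table missing column(s): ",
                            paste(miss, collapse = ", ")))
  key <- interaction(tracks$participant_id, tracks$vowel, tracks$trial_index,
                     drop = TRUE)
  out <- lapply(split(tracks, key), function(tr) {
    tr <- tr[order(tr$time_ms), , drop = FALSE]
    d <- max(tr$time_ms)
    row <- data.frame(participant_id = tr$participant_id[1],
                      vowel = tr$vowel[1], trial_index = tr$trial_index[1],
                      f1_init = NA_real_, f2_init = NA_real_,
                      f1_mid = NA_real_, f2_mid = NA_real_,
                      duration_ms = d, excluded = FALSE,
                      stringsAsFactors = FALSE)
    wa <- tryCatch(window_average(tr$time_ms, tr$f1_hz, tr$f2_hz, d, config),
                   vpp_error = function(e) NULL)
    if (is.null(wa)) row$excluded <- TRUE else row[names(wa)] <- as.list(wa)
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out <- out[order(out$participant_id, out$vowel, out$trial_index), ,
             drop = FALSE]
  rownames(out) <- NULL
  validate_production(out, allow_na_excluded = TRUE)
}
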