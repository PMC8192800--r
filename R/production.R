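# Production measures. All operate on a validated token table (mel units)
# for ONE participant; excluded tokens are dropped before any statistic.

active_tokens <- function(tokens) {
  tokens[!tokens$excluded, , drop = FALSE]
}

split_vowels <- function(tokens) {
  tokens <- active_tokens(tokens)
  split(tokens, factor(tokens$vowel, levels = VOWELS))
}

#' Vowel contrast distance
#'
#' Euclidean distance in mel (F1, F2) space between the two vowels' mean
#' midpoint formants, natural-log-transformed. Larger values mean the
#' speaker keeps the two vowel categories further apart.
#'
#' @param tokens One participant's production token table (mel), with at
#'   least one non-excluded token per vowel.
#' @param log Return the natural log of the distance (default TRUE, the
#'   reported scale).
#' @return Log mel distance (or mel distance when `log = FALSE`).
#' @export
contrast_distance <- function(tokens, log = TRUE) {
  by_v <- split_vowels(tokens)
  if (any(vapply(by_v, nrow, 1L) < 1L))
    vpp_precondition_error("need >= 1 non-excluded token for each vowel")
  cent <- vapply(by_v, function(d) c(mean(d$f1_mid), mean(d$f2_mid)),
                 numeric(2))
  dist <- sqrt(sum((cent[, 1] - cent[, 2])^2))
  if (!log) return(dist)
  if (dist <= 0)
    vpp_degenerate_error("identical vowel centroids: log distance undefined")
  base::log(dist)
}

#' Coverage-ellipse area of one vowel's token cloud
#'
#' Area of the ellipse covering a given probability mass of the bivariate
#' (F1, F2) midpoint distribution:
#' \deqn{A = \pi \, q \, \sqrt{\det S}}
#' where S is the sample covariance (denominator n - 1) of the midpoint
#' formants and q the chi-square(2) quantile at the coverage level
#' (q ~ 5.991 at 0.95). This is the data ellipse of token-to-token scatter,
#' not the standard-error ellipse of the mean.
#'
#' @param tokens Token table rows for a single vowel (>= 3 non-excluded).
#' @param coverage Probability mass the ellipse covers, in (0, 1).
#' @return Area in squared mel.
#' @export
ellipse_area <- function(tokens, coverage = 0.95) {
  if (coverage <= 0 || coverage >= 1)
    vpp_domain_error("coverage must lie strictly in (0, 1)")
  tokens <- active_tokens(tokens)
  if (length(unique(tokens$vowel)) > 1L)
    vpp_precondition_error("ellipse_area expects tokens of a single vowel")
  if (nrow(tokens) < 3L)
    vpp_precondition_error("need >= 3 non-excluded tokens for a covariance")
  S <- var(cbind(tokens$f1_mid, tokens$f2_mid))
  dt <- det(S)
  if (!is.finite(dt) || dt <= .Machine$double.eps)
    vpp_degenerate_error("singular formant covariance: ellipse degenerate")
  pi * qchisq(coverage, df = 2) * sqrt(dt)
}

#' Log mean ellipse area across the two vowels
#'
#' The per-vowel coverage-ellipse areas are averaged arithmetically and then
#' natural-log-transformed — the participant-level trial-to-trial production
#' variability measure.
#'
#' @param tokens One participant's token table containing both vowels.
#' @inheritParams ellipse_area
#' @return Log of the mean area (log squared-mel).
#' @export
mean_log_ellipse_area <- function(tokens, coverage = 0.95) {
  by_v <- split_vowels(tokens)
  areas <- vapply(by_v, ellipse_area, numeric(1), coverage = coverage)
  base::log(mean(areas))
}

#' Per-token centering statistics
#'
#' For each utterance, `d_init` is the Euclidean distance from its initial
#' (F1, F2) values to the per-formant medians of the initial values;
#' `d_mid` the same at midpoint; `centering = d_init - d_mid`. Positive
#' centering means the token moved toward the speaker's median between
#' onset and midpoint (within-utterance self-correction).
#'
#' @param tokens Token table rows for a single participant and vowel.
#' @param centers Optional list with numeric length-2 elements `init` and
#'   `mid` giving reference (F1, F2) centers in mel; when omitted (the
#'   standard analysis) the per-formant medians of `tokens` are used.
#' @return Data frame with columns `d_init, d_mid, centering`, one row per
#'   non-excluded token.
#' @export
token_centering <- function(tokens, centers = NULL) {
  tokens <- active_tokens(tokens)
  if (length(unique(tokens$vowel)) > 1L)
    vpp_precondition_error("token_centering expects tokens of a single vowel")
  if (nrow(tokens) < 1L) vpp_precondition_error("no non-excluded tokens")
  if (is.null(centers))
    centers <- list(init = c(median(tokens$f1_init), median(tokens$f2_init)),
                    mid  = c(median(tokens$f1_mid),  median(tokens$f2_mid)))
  d_init <- sqrt((tokens$f1_init - centers$init[1])^2 +
                 (tokens$f2_init - centers$init[2])^2)
  d_mid  <- sqrt((tokens$f1_mid - centers$mid[1])^2 +
                 (tokens$f2_mid - centers$mid[2])^2)
  data.frame(d_init = d_init, d_mid = d_mid, centering = d_init - d_mid)
}

#' Centering ratio
#'
#' Per vowel, mean centering normalized by mean initial distance,
#' `1 - mean(d_mid) / mean(d_init)`; the participant's final measure is the
#' average of the two per-vowel ratios. 1 = complete correction to the
#' median by midpoint, 0 = none, negative = drift away from the median.
#' The normalization accounts for speakers with little onset variability
#' having less room to correct.
#'
#' @param tokens One participant's token table with >= 3 non-excluded
#'   tokens per vowel.
#' @param centers Optional named list (`EH`, `AE`) of reference centers as
#'   in [token_centering()]; used mainly for generator-truth checks.
#' @return Dimensionless ratio, always <= 1.
#' @export
centering_ratio <- function(tokens, centers = NULL) {
  by_v <- split_vowels(tokens)
  if (any(vapply(by_v, nrow, 1L) < 3L))
    vpp_precondition_error("need >= 3 non-excluded tokens for each vowel")
  ratios <- vapply(names(by_v), function(v) {
    tc <- token_centering(by_v[[v]], centers = centers[[v]])
    mi <- mean(tc$d_init)
    if (mi <= 0)
      vpp_degenerate_error(paste0("mean initial distance is zero for vowel ", v))
    1 - mean(tc$d_mid) / mi
  }, numeric(1))
  mean(ratios)
}

#' Per-vowel production summary
#'
#' Convenience summary of one participant's tokens for one vowel: token
#' count, midpoint centroid and covariance, ellipse area, per-window
#' medians, and the centering components.
#'
#' @inheritParams ellipse_area
#' @return A list of class `"vowel_summary"`.
#' @export
vowel_summary <- function(tokens, coverage = 0.95) {
  tokens <- active_tokens(tokens)
  if (length(unique(tokens$vowel)) != 1L)
    vpp_precondition_error("vowel_summary expects tokens of a single vowel")
  tc <- token_centering(tokens)
  n <- nrow(tokens)
  area <- if (n >= 3L)
    tryCatch(ellipse_area(tokens, coverage), vpp_error = function(e) NA_real_)
  else NA_real_
  structure(list(
    vowel = tokens$vowel[1], n_tokens = n,
    centroid_mid = c(f1 = mean(tokens$f1_mid), f2 = mean(tokens$f2_mid)),
    cov_mid = if (n >= 2L) var(cbind(tokens$f1_mid, tokens$f2_mid)) else NULL,
    ellipse_area = area,
    median_init = c(f1 = median(tokens$f1_init), f2 = median(tokens$f2_init)),
    median_mid  = c(f1 = median(tokens$f1_mid),  f2 = median(tokens$f2_mid)),
    mean_d_init = mean(tc$d_init), mean_d_mid = mean(tc$d_mid),
    mean_centering = mean(tc$centering),
    centering_ratio_vowel = 1 - mean(tc$d_mid) / mean(tc$d_init)
  ), class = "vowel_summary")
}

#' @export
print.vowel_summary <- function(x, ...) {
  cat(sprintf("vowel %s: %d tokens, midpoint centroid (%.1f, %.1f) mel\n",
              x$vowel, x$n_tokens, x$centroid_mid[1], x$centroid_mid[2]))
  cat(sprintf("  ellipse area %.1f mel^2; centering %.2f mel (ratio %.3f)\n",
              x$ellipse_area, x$mean_centering, x$centering_ratio_vowel))
  invisible(x)
}
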