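# Cohort-level screening, descriptives, and the correlation suite.
# A cohort table is a measures data frame (see write_measures_table) plus
# screening columns `included` (logical) and `exclusion_reason` (character).

MEASURE_LABELS <- c(
  labeling_consistency  = "categorical labeling consistency (continuum steps)",
  log_contrast_distance = "vowel contrast distance (log mel)",
  log_ellipse_area      = "area of the ellipse (log squared mel)",
  centering_ratio       = "centering ratio")

#' Shapiro-Wilk normality test
#'
#' Thin, validated wrapper around the standard Shapiro-Wilk algorithm, used
#' to decide whether cohort screening may assume normality (it motivates the
#' MAD-based outlier rule rather than an SD-based one).
#'
#' @param values Numeric vector, 3 <= n <= 5000, non-constant.
#' @return List with elements `W` and `p_value`.
#' @export
normality_test <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 3L || n > 5000L)
    vpp_range_error("Shapiro-Wilk requires 3 <= n <= 5000")
  if (diff(range(values)) == 0)
    vpp_degenerate_error("constant input: normality test undefined")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p_value = sw$p.value)
}

#' MAD outlier screening of a cohort
#'
#' For each named measure, a participant is excluded when their value lies
#' strictly more than `k` MADs from the cohort median of that measure, with
#' both median and MAD computed on the full pre-exclusion cohort (one-shot
#' screening, not iterated). The MAD is raw by default (`constant = 1`, no
#' normal-consistency scaling). Reasons record every measure a participant
#' violated, so overlap between the per-measure exclusion sets is explicit.
#'
#' @param measures A per-participant measures data frame.
#' @param variables Measure columns to screen. Default: the three screened
#'   measures of [analysis_config()].
#' @param k MAD multiplier (default 2).
#' @param constant Scale constant for the MAD (default 1 = raw MAD;
#'   1.4826 for normal consistency).
#' @return The input with logical `included` and character
#'   `exclusion_reason` columns (comma-separated measure names, `""` for
#'   included participants).
#' @export
#' @examples
#' m <- data.frame(participant_id = letters[1:6],
#'                 v = c(5.0, 5.1, 4.9, 5.2, 4.8, 9.0))
#' mad_outlier_filter(m, "v")   # excludes only the 9.0 participant
mad_outlier_filter <- function(measures,
                               variables = analysis_config()$mad_variables,
                               k = 2, constant = 1) {
  if (k <= 0) vpp_domain_error("k must be positive")
  miss <- setdiff(variables, names(measures))
  if (length(miss))
    vpp_schema_error(paste0("measure column(s) not present: ",
                            paste(miss, collapse = ", ")))
  reasons <- rep("", nrow(measures))
  for (v in variables) {
    x <- measures[[v]]
    med <- median(x)
    mad_v <- constant * median(abs(x - med))
    if (mad_v == 0)
      vpp_degenerate_error(paste0("MAD is zero for measure '", v, "'"))
    out <- abs(x - med) > k * mad_v            # strict: exactly k MADs kept
    reasons <- ifelse(out, ifelse(reasons == "", v, paste(reasons, v, sep = ",")),
                      reasons)
  }
  measures$included <- reasons == ""
  measures$exclusion_reason <- reasons
  measures
}

#' Cohort descriptive statistics
#'
#' Mean, SD (n - 1 denominator), minimum and maximum of each measure over
#' the included participants.
#'
#' @param cohort A cohort table; rows with `included = FALSE` are ignored
#'   (a table without an `included` column is taken as all included).
#' @param variables Measure columns to summarize.
#' @return Data frame with columns `measure, mean, sd, min, max, n`.
#' @export
descriptive_stats <- function(cohort, variables = names(MEASURE_LABELS)) {
  if (!is.null(cohort$included)) cohort <- cohort[cohort$included, , drop = FALSE]
  variables <- intersect(variables, names(cohort))
  if (nrow(cohort) < 2L)
    vpp_precondition_error("need >= 2 included participants for descriptives")
  rows <- lapply(variables, function(v) {
    x <- cohort[[v]]
    data.frame(measure = v, mean = mean(x), sd = sd(x),
               min = min(x), max = max(x), n = length(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' rho is the Pearson correlation of mid-ranks (ties receive average
#' ranks); the two-sided p-value uses the t approximation
#' \eqn{t = \rho \sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of freedom.
#'
#' @param x,y Paired numeric vectors, equal length >= 4.
#' @param pair Optional label for the variable pair.
#' @return A list of class `"correlation_result"`: `pair, rho, n, df,
#'   p_value`.
#' @export
spearman_cor <- function(x, y, pair = NULL) {
  if (length(x) != length(y))
    vpp_validation_error("x and y must have equal length")
  n <- length(x)
  if (n < 4L) vpp_precondition_error("need n >= 4 paired observations")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    vpp_validation_error("inputs must be finite")
  if (diff(range(x)) == 0 || diff(range(y)) == 0)
    vpp_degenerate_error("constant vector: rank correlation undefined")
  rho <- cor(rank(x, ties.method = "average"),
             rank(y, ties.method = "average"))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  structure(list(pair = pair %||% "x ~ y", rho = rho, n = n, df = n - 2L,
                 p_value = p),
            class = "correlation_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("%s: rho(%d) = %.2f, p = %.3g\n", x$pair, x$df, x$rho,
              x$p_value))
  invisible(x)
}

#' The perception-production correlation suite
#'
#' Runs the three planned Spearman tests relating categorical labeling
#' consistency to each production measure: log contrast distance, log
#' ellipse area, and centering ratio. p-values are reported unadjusted;
#' readers should keep the three-test multiplicity in mind.
#'
#' @param cohort A screened cohort table (only `included` rows are used).
#' @return Data frame with one row per pair: `pair, rho, n, df, p_value`.
#' @export
run_correlation_suite <- function(cohort) {
  if (!is.null(cohort$included)) cohort <- cohort[cohort$included, , drop = FALSE]
  pairs <- c("log_contrast_distance", "log_ellipse_area", "centering_ratio")
  rows <- lapply(pairs, function(v) {
    r <- spearman_cor(cohort$labeling_consistency, cohort[[v]],
                      pair = paste0("labeling_consistency ~ ", v))
    data.frame(pair = r$pair, rho = r$rho, n = r$n, df = r$df,
               p_value = r$p_value, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
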