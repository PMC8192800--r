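# Pipeline orchestration: per-participant measures, cohort screening,
# descriptives and correlations, plus run-directory entry points with a
# machine-readable run record (the audit trail for every exclusion).

#' Compute the four per-participant measures
#'
#' Joins one production table and one identification table by participant
#' and computes, for every participant present in both: categorical
#' labeling consistency (boundary width), log vowel contrast distance, log
#' mean ellipse area, and centering ratio. Participants present in only one
#' table, or whose measures fail a precondition (e.g. too few usable
#' tokens), are reported in the `incomplete` element — never silently
#' dropped.
#'
#' @param production Validated production token table (mel).
#' @param identification Validated identification trial table.
#' @param config An [analysis_config()].
#' @return List with `measures` (data frame, one row per complete
#'   participant, including `boundary` and token counts) and `incomplete`
#'   (data frame `participant_id, reason`).
#' @export
participant_measures <- function(production, identification,
                                 config = analysis_config()) {
  by_p <- split(production, production$participant_id)
  by_i <- split(identification, identification$participant_id)
  all_ids <- sort(union(names(by_p), names(by_i)))
  meas <- list(); incomplete <- list()
  for (id in all_ids) {
    if (is.null(by_p[[id]])) {
      incomplete[[id]] <- "missing from production table"; next
    }
    if (is.null(by_i[[id]])) {
      incomplete[[id]] <- "missing from identification table"; next
    }
    tok <- by_p[[id]]
    tri <- by_i[[id]]
    row <- tryCatch({
      fit <- fit_psychometric(tri, config)
      data.frame(
        participant_id = id,
        labeling_consistency = labeling_consistency(fit,
                                                    allow_unconverged = TRUE),
        log_contrast_distance = contrast_distance(tok),
        log_ellipse_area = mean_log_ellipse_area(tok,
                                                 config$ellipse_coverage),
        centering_ratio = centering_ratio(tok),
        boundary = boundary_location(fit, allow_unconverged = TRUE),
        n_tokens_eh = sum(tok$vowel == "EH" & !tok$excluded),
        n_tokens_ae = sum(tok$vowel == "AE" & !tok$excluded),
        n_excluded_tokens = sum(tok$excluded),
        n_trials = nrow(tri),
        stringsAsFactors = FALSE)
    }, vpp_error = function(e) conditionMessage(e))
    if (is.character(row)) incomplete[[id]] <- row else meas[[id]] <- row
  }
  measures <- if (length(meas)) do.call(rbind, meas) else
    data.frame(participant_id = character(0))
  rownames(measures) <- NULL
  incomplete <- if (length(incomplete)) {
    data.frame(participant_id = names(incomplete),
               reason = unlist(incomplete, use.names = FALSE),
               stringsAsFactors = FALSE)
  } else {
    data.frame(participant_id = character(0), reason = character(0),
               stringsAsFactors = FALSE)
  }
  list(measures = measures, incomplete = incomplete)
}

#' Run the full cohort analysis in memory
#'
#' The complete analysis: per-participant measures, Shapiro-Wilk normality
#' checks of each measure, one-shot MAD outlier screening, Table-1-style
#' descriptives over the included participants, and the three-pair Spearman
#' correlation suite.
#'
#' @inheritParams participant_measures
#' @return List of class `"cohort_analysis"`: `measures`, `incomplete`,
#'   `normality` (per measure W and p), `cohort` (measures + screening
#'   columns), `descriptives`, `correlations`, `counts`.
#' @export
analyze_cohort <- function(production, identification,
                           config = analysis_config()) {
  pm <- participant_measures(production, identification, config)
  if (nrow(pm$measures) < 4L)
    vpp_precondition_error("need >= 4 complete participants for cohort analysis")
  normality <- do.call(rbind, lapply(names(MEASURE_LABELS), function(v) {
    nt <- tryCatch(normality_test(pm$measures[[v]]),
                   vpp_error = function(e) list(W = NA_real_, p_value = NA_real_))
    data.frame(measure = v, W = nt$W, p_value = nt$p_value,
               stringsAsFactors = FALSE)
  }))
  cohort <- mad_outlier_filter(pm$measures, config$mad_variables,
                               k = config$mad_k,
                               constant = config$mad_consistency_constant)
  desc <- descriptive_stats(cohort)
  corr <- run_correlation_suite(cohort)
  counts <- list(
    n_input = nrow(pm$measures) + nrow(pm$incomplete),
    n_complete = nrow(pm$measures),
    n_incomplete = nrow(pm$incomplete),
    n_included = sum(cohort$included),
    n_screened_out = sum(!cohort$included),
    n_excluded_tokens = sum(pm$measures$n_excluded_tokens),
    # window-overlap bookkeeping: geometric flag vs duration threshold
    n_tokens_overlap = sum(flag_window_overlap(
      production$duration_ms[production$duration_ms > 0], config)),
    n_tokens_short = sum(production$duration_ms < config$overlap_duration_ms),
    overlap_duration_ms = config$overlap_duration_ms)
  structure(list(measures = pm$measures, incomplete = pm$incomplete,
                 normality = normality, cohort = cohort,
                 descriptives = desc, correlations = corr, counts = counts),
            class = "cohort_analysis")
}

#' @export
print.cohort_analysis <- function(x, ...) {
  cat(format_report(x), sep = "\n")
  invisible(x)
}

format_report <- function(an) {
  co <- an$counts
  lines <- c(
    "Perception-production cohort analysis",
    sprintf("  participants: %d input, %d complete, %d incomplete",
            co$n_input, co$n_complete, co$n_incomplete),
    sprintf("  MAD screening: %d excluded, %d included (tokens excluded upstream: %d)",
            co$n_screened_out, co$n_included, co$n_excluded_tokens),
    sprintf("  token windows: %d geometric overlaps, %d shorter than %g ms",
            co$n_tokens_overlap, co$n_tokens_short, co$overlap_duration_ms))
  ex <- an$cohort[!an$cohort$included, , drop = FALSE]
  if (nrow(ex))
    lines <- c(lines, sprintf("    excluded %s (%s)", ex$participant_id,
                              ex$exclusion_reason))
  lines <- c(lines, "", "Descriptives (included participants):")
  d <- an$descriptives
  lines <- c(lines, sprintf("  %-22s mean %8.3f  sd %7.3f  min %8.3f  max %8.3f",
                            d$measure, d$mean, d$sd, d$min, d$max))
  lines <- c(lines, "", "Spearman correlations (unadjusted p; 3 planned tests):")
  r <- an$correlations
  lines <- c(lines, sprintf("  %-45s rho(%d) = %6.3f, p = %.3f",
                            r$pair, r$df, r$rho, r$p_value))
  lines
}

file_digest <- function(path) unname(tools::md5sum(path))

write_run_record <- function(record, dir) {
  path <- file.path(dir, "run_record.json")
  jsonlite::write_json(record, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", force = TRUE)
  invisible(path)
}

#' Simulate a cohort into a run directory
#'
#' Generates a synthetic study dataset (production, identification and
#' ground-truth CSVs) under `out_dir` together with a JSON run record of
#' parameters, seed and file digests. Repeated runs with the same arguments
#' produce identical files.
#'
#' @param out_dir Output directory.
#' @param n_participants,coupling,seed Passed to [cohort_truth()].
#' @param config An [analysis_config()].
#' @return Invisibly, the named vector of file paths.
#' @export
run_simulate <- function(out_dir, n_participants = 37L, coupling = 0,
                         seed = 20260101, config = analysis_config()) {
  truth <- cohort_truth(n_participants = n_participants, coupling = coupling,
                        seed = seed, reps_per_step = config$reps_per_step,
                        n_steps = config$n_steps)
  sim <- simulate_cohort(truth)
  paths <- write_cohort(sim, out_dir)
  write_config(config, file.path(out_dir, "config.json"))
  write_run_record(list(
    stage = "simulate", seed = seed, n_participants = n_participants,
    coupling = coupling, config = unclass(config),
    outputs = as.list(paths),
    digests = lapply(as.list(paths), file_digest)), out_dir)
  invisible(paths)
}

#' Analyze a dataset from files into a run directory
#'
#' Reads the two input tables, runs [analyze_cohort()], and writes:
#' `measures.csv`, `cohort.csv` (screening flags and reasons),
#' `descriptives.csv`, `correlations.csv`, `incomplete.csv`, a
#' human-readable `report.txt`, and a JSON run record with input digests
#' and per-stage counts.
#'
#' @param production_path,identification_path Input CSV paths.
#' @param out_dir Output directory.
#' @param config An [analysis_config()], or a path to a config JSON.
#' @return The `"cohort_analysis"` object, invisibly.
#' @export
run_analyze <- function(production_path, identification_path, out_dir,
                        config = analysis_config()) {
  if (is.character(config)) config <- read_config(config)
  production <- read_production_table(production_path, config)
  identification <- read_identification_table(identification_path, config)
  an <- analyze_cohort(production, identification, config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_measures_table(an$measures, file.path(out_dir, "measures.csv"))
  write.csv(an$cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
  write.csv(an$descriptives, file.path(out_dir, "descriptives.csv"),
            row.names = FALSE)
  write.csv(an$correlations, file.path(out_dir, "correlations.csv"),
            row.names = FALSE)
  write.csv(an$incomplete, file.path(out_dir, "incomplete.csv"),
            row.names = FALSE)
  writeLines(format_report(an), file.path(out_dir, "report.txt"))
  write_run_record(list(
    stage = "analyze",
    inputs = list(production = production_path,
                  identification = identification_path),
    digests = list(production = file_digest(production_path),
                   identification = file_digest(identification_path)),
    config = unclass(config), counts = an$counts,
    outputs = file.path(out_dir, c("measures.csv", "cohort.csv",
                                   "descriptives.csv", "correlations.csv",
                                   "incomplete.csv", "report.txt"))), out_dir)
  invisible(an)
}

#' Summarize a completed analysis run
#'
#' Re-reads the outputs of [run_analyze()] in `run_dir` and returns the
#' human-readable summary (participant counts, exclusions, descriptives,
#' and the three correlations with their degrees of freedom).
#'
#' @param run_dir Directory written by [run_analyze()].
#' @return Character vector of report lines (also printed).
#' @export
run_report <- function(run_dir) {
  need <- file.path(run_dir, c("report.txt", "cohort.csv",
                               "correlations.csv"))
  missing <- need[!file.exists(need)]
  if (length(missing))
    vpp_io_error(paste0("incomplete run directory; missing: ",
                        paste(basename(missing), collapse = ", ")))
  lines <- readLines(file.path(run_dir, "report.txt"))
  cat(lines, sep = "\n")
  invisible(lines)
}
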