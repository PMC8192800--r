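# Synthetic cohort generator. Every stage of the pipeline is testable
# against known ground truth: listeners respond from a true logistic with
# boundary x0_true and scale s_true; speakers draw onset formant deviations
# from a bivariate Gaussian and correct a fraction g ("gain") of that
# deviation by vowel midpoint, plus fresh midpoint noise:
#   init = mu + delta,        delta ~ N(0, onset_cov)
#   mid  = mu + (1 - g) delta + eps,  eps ~ N(0, mid_noise_cov)
# In the noiseless limit the population centering ratio equals g exactly.

check_cov2 <- function(S, what) {
  S <- as.matrix(S)
  if (!all(dim(S) == c(2L, 2L)) || any(!is.finite(S)) ||
      abs(S[1, 2] - S[2, 1]) > 1e-8 * (1 + max(abs(S))) ||
      min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-8)
    vpp_validation_error(paste0(what, " must be a symmetric PSD 2x2 matrix"))
  (S + t(S)) / 2
}

rmvnorm2 <- function(n, mu, Sigma) {
  if (all(Sigma == 0)) return(matrix(mu, n, 2, byrow = TRUE))
  MASS::mvrnorm(n, mu = mu, Sigma = Sigma)
}

rnorm_trunc0 <- function(n, mean, sd) {
  # inverse-CDF sampling of N(mean, sd) truncated to (0, Inf)
  p0 <- pnorm(0, mean, sd)
  qnorm(p0 + runif(n) * (1 - p0), mean, sd)
}

#' Listener ground-truth parameters
#'
#' @param x0 True categorical boundary, in continuum steps.
#' @param s True logistic scale in steps (> 0); the true boundary width is
#'   `2 * s * log(3)`.
#' @param n_steps,reps_per_step Identification design (defaults 11 x 20).
#' @return List of class `"listener_params"`.
#' @export
listener_params <- function(x0 = 6, s = 0.6, n_steps = 11L,
                            reps_per_step = 20L) {
  if (s <= 0) vpp_validation_error("s must be positive")
  if (reps_per_step < 1L) vpp_validation_error("reps_per_step must be >= 1")
  structure(list(x0 = x0, s = s, n_steps = as.integer(n_steps),
                 reps_per_step = as.integer(reps_per_step)),
            class = "listener_params")
}

#' Speaker ground-truth parameters for one vowel
#'
#' @param onset_mean Length-2 (F1, F2) mean at vowel onset, mel.
#' @param onset_sd Scalar SD (mel) used to build an isotropic onset
#'   covariance, or ignored when `onset_cov` is given.
#' @param onset_cov Optional full 2x2 onset covariance (mel^2).
#' @param gain Correction gain g in [0, 1]: the fraction of the onset
#'   deviation removed by midpoint.
#' @param mid_noise_sd,mid_noise_cov Midpoint noise, same conventions.
#' @param n_tokens Tokens per vowel (default 45).
#' @param duration_mean,duration_sd Token duration distribution, ms
#'   (Gaussian truncated at 0).
#' @return List of class `"speaker_params"`.
#' @export
speaker_params <- function(onset_mean, onset_sd = 20, onset_cov = NULL,
                           gain = 0.1, mid_noise_sd = 8,
                           mid_noise_cov = NULL, n_tokens = 45L,
                           duration_mean = 200, duration_sd = 30) {
  if (gain < 0 || gain > 1) vpp_validation_error("gain must lie in [0, 1]")
  if (is.null(onset_cov)) onset_cov <- diag(onset_sd^2, 2)
  if (is.null(mid_noise_cov)) mid_noise_cov <- diag(mid_noise_sd^2, 2)
  structure(list(
    onset_mean = as.numeric(onset_mean),
    onset_cov = check_cov2(onset_cov, "onset_cov"),
    gain = gain,
    mid_noise_cov = check_cov2(mid_noise_cov, "mid_noise_cov"),
    n_tokens = as.integer(n_tokens),
    duration_mean = duration_mean, duration_sd = duration_sd
  ), class = "speaker_params")
}

#' Build the synthesized continuum design
#'
#' An `n_full`-step equally spaced (F1, F2) grid between two endpoint
#' tokens, from which `n_select` steps are chosen with denser sampling in
#' the middle 50% of the continuum length (where the categorical boundary
#' is expected), so interior step-to-step frequency gaps are smaller than
#' the endpoint-adjacent gaps.
#'
#' @param endpoints List of two length-2 (F1, F2) Hz vectors (the natural
#'   "head" and "had" tokens).
#' @param n_full Size of the full equally spaced continuum (default 41).
#' @param n_select Steps selected for presentation (default 11).
#' @param seed Unused source of randomness kept for interface stability;
#'   the selection is deterministic.
#' @return List of class `"continuum_design"`: `n_steps`, `f1_hz`, `f2_hz`,
#'   `selected_index` (into the full grid), `tighter_interior` flag.
#' @export
make_continuum_design <- function(endpoints, n_full = 41L, n_select = 11L,
                                  seed = NULL) {
  a <- as.numeric(endpoints[[1]]); b <- as.numeric(endpoints[[2]])
  if (length(a) != 2L || length(b) != 2L)
    vpp_validation_error("endpoints must be two (F1, F2) pairs")
  if (all(a == b)) vpp_precondition_error("continuum endpoints must differ")
  if (n_select > n_full) vpp_range_error("n_select cannot exceed n_full")
  if (n_select < 2L) vpp_range_error("n_select must be >= 2")
  t_full <- seq(0, 1, length.out = n_full)
  if (n_select == n_full) {
    idx <- seq_len(n_full)
  } else if (n_select >= 5L) {
    # endpoints, two shoulders, remaining steps equal-spaced in the middle 50%
    interior <- seq(0.25, 0.75, length.out = n_select - 4L)
    target <- c(0, 0.125, interior, 0.875, 1)
    idx <- vapply(target, function(tt) which.min(abs(t_full - tt)), 1L)
    idx <- sort(unique(idx))
    # snapping collisions (tiny grids): fall back to even selection
    if (length(idx) != n_select)
      idx <- round(seq(1, n_full, length.out = n_select))
  } else {
    idx <- round(seq(1, n_full, length.out = n_select))
  }
  structure(list(
    n_steps = n_select,
    f1_hz = a[1] + t_full[idx] * (b[1] - a[1]),
    f2_hz = a[2] + t_full[idx] * (b[2] - a[2]),
    selected_index = idx,
    tighter_interior = n_select != n_full && n_select >= 5L
  ), class = "continuum_design")
}

#' Simulate one listener's identification responses
#'
#' Each of the `n_steps` continuum steps is presented `reps_per_step` times
#' in randomized order; each HEAD response is an independent Bernoulli draw
#' with probability `plogis((x0 - step)/s)`.
#'
#' @param listener A [listener_params()].
#' @param design Optional [make_continuum_design()]; only its step count is
#'   used (the fit works in step indices, not Hz).
#' @param seed Integer seed; same seed, same trials.
#' @param participant_id Label written into the table.
#' @return Identification data frame `participant_id, step, response`.
#' @export
simulate_identification <- function(listener, design = NULL, seed = NULL,
                                    participant_id = "P01") {
  stopifnot(inherits(listener, "listener_params"))
  n_steps <- if (!is.null(design)) design$n_steps else listener$n_steps
  if (!is.null(seed)) set.seed(seed)
  steps <- rep(seq_len(n_steps), each = listener$reps_per_step)
  steps <- sample(steps)
  p_head <- plogis((listener$x0 - steps) / listener$s)
  resp <- ifelse(rbinom(length(steps), 1L, p_head) == 1L, "HEAD", "HAD")
  data.frame(participant_id = participant_id, step = steps,
             response = factor(resp, levels = c("HEAD", "HAD")),
             stringsAsFactors = FALSE)
}

#' Simulate one speaker's production tokens for one vowel
#'
#' @param speaker A [speaker_params()].
#' @param vowel `"EH"` or `"AE"`.
#' @param seed Integer seed.
#' @param participant_id Label written into the table.
#' @return Production token data frame (mel), `excluded` all FALSE.
#' @export
simulate_speaker <- function(speaker, vowel = "EH", seed = NULL,
                             participant_id = "P01") {
  stopifnot(inherits(speaker, "speaker_params"))
  if (!vowel %in% VOWELS) vpp_validation_error("vowel must be EH or AE")
  if (!is.null(seed)) set.seed(seed)
  n <- speaker$n_tokens
  delta <- rmvnorm2(n, c(0, 0), speaker$onset_cov)
  eps <- rmvnorm2(n, c(0, 0), speaker$mid_noise_cov)
  init <- sweep(delta, 2, speaker$onset_mean, "+")
  mid <- sweep((1 - speaker$gain) * delta + eps, 2, speaker$onset_mean, "+")
  data.frame(
    participant_id = participant_id, vowel = vowel, trial_index = seq_len(n),
    f1_init = init[, 1], f2_init = init[, 2],
    f1_mid = mid[, 1], f2_mid = mid[, 2],
    duration_ms = rnorm_trunc0(n, speaker$duration_mean, speaker$duration_sd),
    excluded = FALSE, stringsAsFactors = FALSE)
}

#' Expand window-averaged tokens into per-frame formant tracks
#'
#' Fixture generator for the preprocessing stage: each token becomes a
#' track (in Hz) that holds its initial value over the initial window,
#' ramps linearly to its midpoint value, and holds that through the
#' midpoint window, with optional per-frame mel-domain noise. With zero
#' noise and non-overlapping windows, window averaging recovers the token
#' values exactly.
#'
#' @param tokens Production token table (mel).
#' @param frame_step_ms Frame spacing, ms.
#' @param frame_noise_sd_mel Per-frame noise SD in mel (default 0).
#' @param seed Integer seed (used only when noise > 0).
#' @param config An [analysis_config()] (mel formula, windows).
#' @return Long data frame `participant_id, vowel, trial_index, time_ms,
#'   f1_hz, f2_hz`.
#' @export
simulate_tracks <- function(tokens, frame_step_ms = 5,
                            frame_noise_sd_mel = 0, seed = NULL,
                            config = analysis_config()) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(nrow(tokens)), function(i) {
    tk <- tokens[i, ]
    d <- tk$duration_ms
    times <- seq(0, d, by = frame_step_ms)
    w_init_end <- min(config$initial_window_ms[2], 0.5 * d)
    w_mid_start <- max(config$midpoint_fraction[1] * d, w_init_end)
    ramp <- pmin(pmax((times - w_init_end) /
                        max(w_mid_start - w_init_end, 1e-9), 0), 1)
    f1 <- tk$f1_init + ramp * (tk$f1_mid - tk$f1_init)
    f2 <- tk$f2_init + ramp * (tk$f2_mid - tk$f2_init)
    if (frame_noise_sd_mel > 0) {
      f1 <- f1 + rnorm(length(times), 0, frame_noise_sd_mel)
      f2 <- f2 + rnorm(length(times), 0, frame_noise_sd_mel)
    }
    data.frame(participant_id = tk$participant_id, vowel = tk$vowel,
               trial_index = tk$trial_index, time_ms = times,
               f1_hz = mel_to_hz(f1, config$mel_formula_id),
               f2_hz = mel_to_hz(f2, config$mel_formula_id),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Draw per-participant ground-truth parameters for a cohort
#'
#' Listener boundary widths follow a truncated Normal spanning the
#' plausible study range; speaker onset dispersion is uniform on a range
#' producing study-scale ellipse areas; correction gains are uniform on
#' [0, 0.27], yielding mostly small positive centering ratios. A Gaussian
#' copula imposes a target Spearman rank correlation (`coupling`) between
#' listener width and speaker onset dispersion; `coupling = 0` gives fully
#' independent perception and production (the null world).
#'
#' @param n_participants Cohort size (default 37).
#' @param coupling Target rank correlation between true boundary width and
#'   onset dispersion, in [-1, 1]. Default 0.
#' @param seed Integer seed.
#' @param n_tokens,reps_per_step,n_steps Design sizes (defaults 45, 20, 11).
#' @return Data frame of class `"cohort_truth"`, one row per participant:
#'   `participant_id, x0_true, s_true, width_true, onset_sd, gain,
#'   eh_f1, eh_f2, ae_f1, ae_f2, mid_noise_sd, dur_eh, dur_ae`, with the
#'   seed and coupling kept as attributes.
#' @export
cohort_truth <- function(n_participants = 37L, coupling = 0, seed = 20260101,
                         n_tokens = 45L, reps_per_step = 20L, n_steps = 11L) {
  if (abs(coupling) > 1) vpp_validation_error("coupling must lie in [-1, 1]")
  set.seed(seed)
  n <- n_participants
  # Gaussian copula: latent Pearson r giving Spearman rho = coupling
  r <- 2 * sin(pi * coupling / 6)
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  u1 <- pnorm(z1); u2 <- pnorm(z2)
  # width ~ Normal(1.89, 0.56) truncated to [0.5, 3.5] via inverse CDF
  plo <- pnorm(0.5, 1.89, 0.56); phi <- pnorm(3.5, 1.89, 0.56)
  width <- qnorm(plo + u1 * (phi - plo), 1.89, 0.56)
  onset_sd <- 16 + 12 * u2
  out <- data.frame(
    participant_id = sprintf("P%02d", seq_len(n)),
    x0_true = rnorm(n, 6, 0.8),
    s_true = width / (2 * log(3)),
    width_true = width,
    onset_sd = onset_sd,
    gain = runif(n, 0, 0.27),
    eh_f1 = rnorm(n, 720, 20), eh_f2 = rnorm(n, 1640, 20),
    ae_f1 = rnorm(n, 860, 20), ae_f2 = rnorm(n, 1540, 20),
    mid_noise_sd = 8,
    dur_eh = 179, dur_ae = 237,
    stringsAsFactors = FALSE)
  structure(out, class = c("cohort_truth", "data.frame"),
            seed = seed, coupling = coupling, n_tokens = as.integer(n_tokens),
            reps_per_step = as.integer(reps_per_step),
            n_steps = as.integer(n_steps))
}

#' Simulate a full cohort dataset
#'
#' Produces the two analysis input tables (production tokens and
#' identification trials) plus the ground-truth parameter table, exactly in
#' the schemas the readers consume. Deterministic: the same truth object
#' yields byte-identical tables.
#'
#' @param truth A [cohort_truth()] data frame (or one of the same shape).
#' @return List of class `"cohort_sim"`: `production`, `identification`,
#'   `ground_truth`.
#' @export
simulate_cohort <- function(truth) {
  seed <- attr(truth, "seed") %||% 1L
  n_tokens <- attr(truth, "n_tokens") %||% 45L
  reps <- attr(truth, "reps_per_step") %||% 20L
  n_steps <- attr(truth, "n_steps") %||% 11L
  prod <- vector("list", nrow(truth)); ident <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    tr <- truth[i, ]
    sub_seed <- (seed + 7919L * i) %% .Machine$integer.max
    li <- listener_params(x0 = tr$x0_true, s = tr$s_true,
                          n_steps = n_steps, reps_per_step = reps)
    ident[[i]] <- simulate_identification(li, seed = sub_seed,
                                          participant_id = tr$participant_id)
    sp_eh <- speaker_params(onset_mean = c(tr$eh_f1, tr$eh_f2),
                            onset_sd = tr$onset_sd, gain = tr$gain,
                            mid_noise_sd = tr$mid_noise_sd,
                            n_tokens = n_tokens,
                            duration_mean = tr$dur_eh)
    sp_ae <- speaker_params(onset_mean = c(tr$ae_f1, tr$ae_f2),
                            onset_sd = tr$onset_sd, gain = tr$gain,
                            mid_noise_sd = tr$mid_noise_sd,
                            n_tokens = n_tokens,
                            duration_mean = tr$dur_ae)
    prod[[i]] <- rbind(
      simulate_speaker(sp_eh, "EH", seed = sub_seed + 1L,
                       participant_id = tr$participant_id),
      simulate_speaker(sp_ae, "AE", seed = sub_seed + 2L,
                       participant_id = tr$participant_id))
  }
  structure(list(production = do.call(rbind, prod),
                 identification = do.call(rbind, ident),
                 ground_truth = as.data.frame(truth)),
            class = "cohort_sim")
}

#' Write a simulated cohort to a directory
#'
#' Writes `production.csv`, `identification.csv` and `ground_truth.csv` in
#' the schemas [read_production_table()] and [read_identification_table()]
#' consume.
#'
#' @param sim A [simulate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(production = file.path(dir, "production.csv"),
             identification = file.path(dir, "identification.csv"),
             ground_truth = file.path(dir, "ground_truth.csv"))
  write.csv(sim$production, paths["production"], row.names = FALSE)
  write.csv(sim$identification, paths["identification"], row.names = FALSE)
  write.csv(sim$ground_truth, paths["ground_truth"], row.names = FALSE)
  invisible(paths)
}
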