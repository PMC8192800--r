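# Shared fixture builders (everything is generated in code; no stored data).

make_tokens <- function(f1_init, f2_init, f1_mid = f1_init,
                        f2_mid = f2_init, vowel = "EH",
                        participant_id = "P01", duration_ms = 220,
                        excluded = FALSE) {
  n <- length(f1_init)
  data.frame(participant_id = participant_id, vowel = vowel,
             trial_index = seq_len(n),
             f1_init = f1_init, f2_init = f2_init,
             f1_mid = f1_mid, f2_mid = f2_mid,
             duration_ms = duration_ms, excluded = excluded,
             stringsAsFactors = FALSE)
}

# n points in 2-D whose SAMPLE covariance is exactly `target` and whose
# sample mean is exactly `center` (whiten then recolor).
exact_cov_cloud <- function(n, target, center = c(0, 0), seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n), n, 2)
  X <- scale(X, center = TRUE, scale = FALSE)
  X <- X %*% solve(chol(var(X)))
  X <- X %*% chol(target)
  sweep(X, 2, center, "+")
}

# token table for both vowels from one simulated speaker configuration
two_vowel_tokens <- function(gain = 0.2, onset_sd = 20, mid_noise_sd = 8,
                             n_tokens = 45, seed = 1) {
  eh <- speaker_params(onset_mean = c(720, 1640), onset_sd = onset_sd,
                       gain = gain, mid_noise_sd = mid_noise_sd,
                       n_tokens = n_tokens, duration_mean = 179)
  ae <- speaker_params(onset_mean = c(860, 1540), onset_sd = onset_sd,
                       gain = gain, mid_noise_sd = mid_noise_sd,
                       n_tokens = n_tokens, duration_mean = 237)
  rbind(simulate_speaker(eh, "EH", seed = seed),
        simulate_speaker(ae, "AE", seed = seed + 1))
}
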