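test_that("continuum design oversamples the middle of the continuum", {
  des <- make_continuum_design(list(c(669, 2349), c(1000, 1679)))
  expect_equal(des$n_steps, 11L)
  expect_true(all(diff(des$f1_hz) > 0))
  expect_true(all(diff(des$f2_hz) < 0))
  gaps <- abs(diff(des$f1_hz))
  interior <- gaps[3:8]            # between steps 3-9
  edges <- gaps[c(1, 2, 9, 10)]    # endpoint-adjacent
  expect_lt(mean(interior), mean(edges))
})

test_that("continuum design handles identity selection and bad input", {
  des <- make_continuum_design(list(c(600, 2300), c(1000, 1700)),
                               n_full = 41, n_select = 41)
  expect_equal(des$f1_hz, seq(600, 1000, length.out = 41))
  expect_error(make_continuum_design(list(c(600, 2300), c(600, 2300))),
               class = "vpp_precondition_error")
  expect_error(make_continuum_design(list(c(600, 2300), c(1000, 1700)),
                                     n_full = 10, n_select = 11),
               class = "vpp_range_error")
})

test_that("simulated identification matches its generating probabilities", {
  li <- listener_params(x0 = 6, s = 0.8, reps_per_step = 10000)
  tr <- simulate_identification(li, seed = 21)
  p_hat <- tapply(tr$response == "HEAD", tr$step, mean)
  p_true <- plogis((6 - 1:11) / 0.8)
  expect_true(all(abs(p_hat - p_true) < 0.01))

  # boundary far left of the continuum: almost everything is HAD
  far <- simulate_identification(listener_params(x0 = -10, s = 0.5), seed = 3)
  expect_gt(mean(far$response == "HAD"), 0.999)
})

test_that("simulated speakers honor the gain mechanism and moments", {
  sp0 <- speaker_params(onset_mean = c(720, 1640), gain = 0, mid_noise_sd = 0)
  t0 <- simulate_speaker(sp0, seed = 1)
  expect_equal(t0$f1_mid, t0$f1_init)
  expect_equal(t0$f2_mid, t0$f2_init)

  sp1 <- speaker_params(onset_mean = c(720, 1640), gain = 1, mid_noise_sd = 0)
  t1 <- simulate_speaker(sp1, seed = 2)
  expect_equal(t1$f1_mid, rep(720, 45))
  expect_equal(unique(t1$f2_mid), 1640)

  # moment matching: sample onset covariance close to the target at n = 10000
  S <- matrix(c(400, 60, 60, 150), 2)
  sp <- speaker_params(onset_mean = c(720, 1640), onset_cov = S,
                       gain = 0.3, n_tokens = 10000)
  tok <- simulate_speaker(sp, seed = 5)
  S_hat <- var(cbind(tok$f1_init, tok$f2_init))
  expect_lt(norm(S_hat - S, "F") / norm(S, "F"), 0.05)

  expect_error(speaker_params(onset_mean = c(720, 1640), gain = 1.5),
               class = "vpp_validation_error")
  expect_error(speaker_params(onset_mean = c(720, 1640),
                              onset_cov = matrix(c(1, 2, 2, 1), 2)),
               class = "vpp_validation_error")
})

test_that("cohort simulation is deterministic and correctly sized", {
  truth <- cohort_truth(n_participants = 37, seed = 77)
  sim1 <- simulate_cohort(truth)
  sim2 <- simulate_cohort(truth)
  expect_identical(sim1, sim2)
  expect_equal(length(unique(sim1$production$participant_id)), 37L)
  expect_equal(length(unique(sim1$identification$participant_id)), 37L)
  expect_equal(nrow(sim1$identification), 37L * 11L * 20L)
  expect_equal(nrow(sim1$production), 37L * 2L * 45L)

  # written files are byte-identical across repeated runs
  d1 <- tempfile(); d2 <- tempfile()
  write_cohort(sim1, d1); write_cohort(sim2, d2)
  for (f in c("production.csv", "identification.csv", "ground_truth.csv"))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
})

test_that("the copula imposes the requested rank coupling", {
  # large single cohort: empirical rank correlation close to the target
  big <- cohort_truth(n_participants = 3000, coupling = 0.8, seed = 13)
  expect_equal(cor(big$width_true, big$onset_sd, method = "spearman"), 0.8,
               tolerance = 0.05)
  # independence at coupling 0: mean rank correlation over cohorts near 0
  rhos <- vapply(1:60, function(i) {
    tr <- cohort_truth(n_participants = 31, coupling = 0, seed = 900 + i)
    cor(tr$width_true, tr$onset_sd, method = "spearman")
  }, numeric(1))
  expect_lt(abs(mean(rhos)), 0.05)
  expect_error(cohort_truth(coupling = 1.5), class = "vpp_validation_error")
})

test_that("pipeline estimates rank-track heterogeneous generating parameters", {
  truth <- cohort_truth(n_participants = 31, coupling = 0, seed = 11)
  set.seed(99)
  truth$s_true <- seq(0.6, 3.4, length.out = 31)[sample(31)] / (2 * log(3))
  truth$width_true <- truth$s_true * 2 * log(3)
  truth$onset_sd <- seq(14, 30, length.out = 31)[sample(31)]
  truth$gain <- seq(0, 0.9, length.out = 31)[sample(31)]
  truth$mid_noise_sd <- 4
  sim <- simulate_cohort(truth)
  pm <- participant_measures(sim$production, sim$identification)
  m <- merge(pm$measures, sim$ground_truth, by = "participant_id")
  q <- qchisq(0.95, 2)
  true_area <- pi * q * ((1 - m$gain)^2 * m$onset_sd^2 + m$mid_noise_sd^2)
  expect_gt(cor(m$labeling_consistency, m$width_true, method = "spearman"), 0.9)
  expect_gt(cor(m$log_ellipse_area, log(true_area), method = "spearman"), 0.9)
  expect_gt(cor(m$centering_ratio, m$gain, method = "spearman"), 0.9)
})

test_that("default cohorts produce study-scale measure distributions", {
  truth <- cohort_truth(n_participants = 37, seed = 2024)
  sim <- simulate_cohort(truth)
  pm <- participant_measures(sim$production, sim$identification)
  m <- pm$measures
  # the generator's stated world: measures inside (roughly) the published
  # cohort ranges, allowing sampling slack at n = 37
  expect_true(mean(m$labeling_consistency) > 1 &&
                mean(m$labeling_consistency) < 3)
  expect_true(mean(m$log_contrast_distance) > 4.6 &&
                mean(m$log_contrast_distance) < 5.5)
  expect_true(mean(m$log_ellipse_area) > 8.0 &&
                mean(m$log_ellipse_area) < 9.7)
  expect_true(mean(m$centering_ratio) > -0.1 &&
                mean(m$centering_ratio) < 0.25)
})
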