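test_that("contrast distance matches the hand-computed example", {
  tok <- rbind(make_tokens(700, 1800, 700, 1800, vowel = "EH"),
               make_tokens(800, 1700, 800, 1700, vowel = "AE"))
  # centroids (700, 1800) and (800, 1700): distance sqrt(2)*100, ln = 4.95174
  expect_equal(contrast_distance(tok, log = FALSE), 141.42136,
               tolerance = 1e-7)
  expect_equal(contrast_distance(tok), 4.9517438, tolerance = 1e-7)
})

test_that("contrast distance rejects degenerate and incomplete input", {
  same <- rbind(make_tokens(700, 1800, vowel = "EH"),
                make_tokens(700, 1800, vowel = "AE"))
  expect_error(contrast_distance(same), class = "vpp_degenerate_error")
  one_vowel <- make_tokens(c(700, 710), c(1800, 1790), vowel = "EH")
  expect_error(contrast_distance(one_vowel), class = "vpp_precondition_error")
})

test_that("ellipse area follows the closed form pi * q * sqrt(det S)", {
  q <- qchisq(0.95, 2)
  cloud <- exact_cov_cloud(40, diag(2), center = c(800, 1600))
  tok <- make_tokens(cloud[, 1] * 0 + 800, cloud[, 2] * 0 + 1600,
                     cloud[, 1], cloud[, 2])
  expect_equal(ellipse_area(tok), pi * q, tolerance = 1e-9)       # ~18.82
  cloud2 <- exact_cov_cloud(40, diag(c(4, 1)), center = c(800, 1600))
  tok2 <- make_tokens(cloud2[, 1] * 0 + 800, cloud2[, 2] * 0 + 1600,
                      cloud2[, 1], cloud2[, 2])
  expect_equal(ellipse_area(tok2), 2 * pi * q, tolerance = 1e-9)  # ~37.64

  ident <- make_tokens(rep(800, 5), rep(1600, 5))
  expect_error(ellipse_area(ident), class = "vpp_degenerate_error")
  expect_error(ellipse_area(tok[1:2, ]), class = "vpp_precondition_error")
})

test_that("mean log ellipse area averages areas before the log", {
  q <- qchisq(0.95, 2)
  # scale whitened clouds so per-vowel areas are exactly 10 and 30
  make_cloud_tok <- function(area, vowel, seed) {
    s2 <- area / (pi * q)
    cl <- exact_cov_cloud(30, diag(s2, 2), center = c(800, 1600), seed = seed)
    make_tokens(rep(800, 30), rep(1600, 30), cl[, 1], cl[, 2], vowel = vowel)
  }
  tok <- rbind(make_cloud_tok(10, "EH", 1), make_cloud_tok(30, "AE", 2))
  expect_equal(mean_log_ellipse_area(tok), log(20), tolerance = 1e-9)
  tok_eq <- rbind(make_cloud_tok(18.82, "EH", 3), make_cloud_tok(18.82, "AE", 4))
  expect_equal(mean_log_ellipse_area(tok_eq), log(18.82), tolerance = 1e-9)
})

test_that("token centering follows the 3-4-5 geometry and sign convention", {
  centers <- list(init = c(700, 1800), mid = c(700, 1800))
  at_center <- make_tokens(700, 1800, 700, 1800)
  tc0 <- token_centering(at_center, centers)
  expect_equal(unlist(tc0), c(d_init = 0, d_mid = 0, centering = 0))

  corrective <- make_tokens(703, 1804, 700, 1800)   # init deviation (3, 4)
  tc1 <- token_centering(corrective, centers)
  expect_equal(tc1$d_init, 5)
  expect_equal(tc1$centering, 5)

  outward <- make_tokens(700, 1800, 703, 1804)      # mid deviation (3, 4)
  tc2 <- token_centering(outward, centers)
  expect_equal(tc2$centering, -5)
})

test_that("centering ratio hits its endpoints and gain exactly when noiseless", {
  # g = 0: no within-utterance change, ratio 0 exactly
  expect_equal(centering_ratio(two_vowel_tokens(gain = 0, mid_noise_sd = 0)), 0)
  # g = 1: all midpoints at the vowel mean, ratio 1 exactly
  expect_equal(centering_ratio(two_vowel_tokens(gain = 1, mid_noise_sd = 0)), 1)
  # intermediate noiseless gain is recovered exactly (medians cancel)
  expect_equal(centering_ratio(two_vowel_tokens(gain = 0.5, mid_noise_sd = 0)),
               0.5, tolerance = 1e-12)
  expect_lte(centering_ratio(two_vowel_tokens(gain = 0.3, seed = 4)), 1)
})

test_that("centering ratio validates sample size and degenerate spread", {
  small <- rbind(make_tokens(c(700, 710), c(1800, 1790), vowel = "EH"),
                 make_tokens(c(860, 870), c(1540, 1530), vowel = "AE"))
  expect_error(centering_ratio(small), class = "vpp_precondition_error")
  flat <- rbind(make_tokens(rep(700, 5), rep(1800, 5), vowel = "EH"),
                make_tokens(rep(860, 5), rep(1540, 5), vowel = "AE"))
  expect_error(centering_ratio(flat), class = "vpp_degenerate_error")
})

test_that("measures are translation invariant and centering is rotation invariant", {
  tok <- two_vowel_tokens(gain = 0.25, seed = 9)
  shifted <- tok
  for (col in c("f1_init", "f1_mid")) shifted[[col]] <- shifted[[col]] + 37
  for (col in c("f2_init", "f2_mid")) shifted[[col]] <- shifted[[col]] - 12
  expect_equal(contrast_distance(shifted), contrast_distance(tok))
  expect_equal(mean_log_ellipse_area(shifted), mean_log_ellipse_area(tok))
  expect_equal(centering_ratio(shifted), centering_ratio(tok))

  # rotate all deviations about a fixed center: distances unchanged
  center <- c(720, 1640)
  eh <- tok[tok$vowel == "EH", ]
  th <- 0.7; R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  rot <- eh
  di <- as.matrix(eh[, c("f1_init", "f2_init")]) -
    matrix(center, nrow(eh), 2, byrow = TRUE)
  dm <- as.matrix(eh[, c("f1_mid", "f2_mid")]) -
    matrix(center, nrow(eh), 2, byrow = TRUE)
  rot[, c("f1_init", "f2_init")] <- di %*% t(R) +
    matrix(center, nrow(eh), 2, byrow = TRUE)
  rot[, c("f1_mid", "f2_mid")] <- dm %*% t(R) +
    matrix(center, nrow(eh), 2, byrow = TRUE)
  centers <- list(init = center, mid = center)
  expect_equal(token_centering(rot, centers), token_centering(eh, centers))
})

test_that("excluded tokens are dropped from every production measure", {
  tok <- two_vowel_tokens(gain = 0.2, seed = 3)
  spiked <- rbind(tok, data.frame(
    participant_id = "P01", vowel = c("EH", "AE"), trial_index = 99L,
    f1_init = 5000, f2_init = 9000, f1_mid = 5000, f2_mid = 9000,
    duration_ms = 200, excluded = TRUE, stringsAsFactors = FALSE))
  expect_equal(contrast_distance(spiked), contrast_distance(tok))
  expect_equal(mean_log_ellipse_area(spiked), mean_log_ellipse_area(tok))
  expect_equal(centering_ratio(spiked), centering_ratio(tok))
})

test_that("vowel_summary assembles consistent per-vowel fields", {
  tok <- two_vowel_tokens(gain = 0.2, seed = 6)
  eh <- tok[tok$vowel == "EH", ]
  vs <- vowel_summary(eh)
  expect_equal(vs$n_tokens, 45L)
  expect_equal(vs$mean_centering, vs$mean_d_init - vs$mean_d_mid)
  expect_lte(vs$centering_ratio_vowel, 1)
  expect_equal(vs$ellipse_area, ellipse_area(eh))
})
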