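test_that("Shapiro-Wilk wrapper matches an independent reference value", {
  # W and p computed once with an independent implementation (scipy.stats
  # .shapiro) on this frozen fixture and hard-coded here.
  x <- c(5.0016, 5.3884, 4.6436, 6.3422, 4.4089, 3.7109, 5.0782, 6.7423,
         4.3601, 4.1934, 5.6368, 5.464, 5.137, 3.7904, 4.962, 5.9039,
         3.2525, 4.4051, 2.5284, 3.3236)
  nt <- normality_test(x)
  expect_equal(nt$W, 0.9909399087, tolerance = 1e-6)
  expect_equal(nt$p_value, 0.9990418123, tolerance = 1e-6)

  expect_error(normality_test(rep(1, 10)), class = "vpp_degenerate_error")
  expect_error(normality_test(c(1, 2)), class = "vpp_range_error")
})

test_that("normality test detects heavy tails", {
  set.seed(31)
  rejected <- vapply(1:40, function(i) {
    normality_test(rcauchy(1000))$p_value < 0.05
  }, logical(1))
  expect_gte(mean(rejected), 0.95)
})

test_that("MAD filter reproduces the hand-computed fixture", {
  m <- data.frame(participant_id = sprintf("P%d", 1:6),
                  v = c(5.0, 5.1, 4.9, 5.2, 4.8, 9.0))
  # median 5.05, raw MAD 0.15, cutoff 0.30: only 9.0 is outside
  got <- mad_outlier_filter(m, "v", k = 2)
  expect_equal(got$included, c(rep(TRUE, 5), FALSE))
  expect_equal(got$exclusion_reason[6], "v")
})

test_that("MAD filter edge behavior: strict cutoff, empty list, zero scale", {
  m <- data.frame(participant_id = sprintf("P%d", 1:5),
                  v = c(5, 6, 7, 8, 9))   # median 7, MAD 1
  got <- mad_outlier_filter(m, "v", k = 2)
  expect_true(all(got$included))  # |9 - 7| == 2 MADs exactly: retained

  got2 <- mad_outlier_filter(m, character(0), k = 2)
  expect_true(all(got2$included))

  # a near-constant measure has MAD 0: a typed degenerate-scale error
  const <- data.frame(participant_id = sprintf("P%d", 1:6),
                      v = c(5, 5, 5, 5, 5, 9))
  expect_error(mad_outlier_filter(const, "v"),
               class = "vpp_degenerate_error")
  expect_error(mad_outlier_filter(m, "nope"), class = "vpp_schema_error")
})

test_that("MAD filter uses pre-exclusion statistics and records all reasons", {
  m <- data.frame(participant_id = sprintf("P%d", 1:7),
                  a = c(5.0, 5.1, 4.9, 5.2, 4.8, 9.0, 5.05),
                  b = c(1.0, 1.1, 0.9, 1.2, 0.8, 5.0, 1.05))
  got <- mad_outlier_filter(m, c("a", "b"), k = 2)
  expect_equal(sum(!got$included), 1L)
  expect_equal(got$exclusion_reason[6], "a,b")
})

test_that("descriptive stats match hand computation and ignore excluded rows", {
  m <- data.frame(participant_id = c("A", "B"),
                  labeling_consistency = c(1, 3))
  d <- descriptive_stats(m, "labeling_consistency")
  expect_equal(unlist(d[, c("mean", "sd", "min", "max")]),
               c(mean = 2, sd = sqrt(2), min = 1, max = 3))

  m2 <- data.frame(participant_id = c("A", "B", "C"),
                   labeling_consistency = c(1, 3, 100),
                   included = c(TRUE, TRUE, FALSE))
  d2 <- descriptive_stats(m2, "labeling_consistency")
  expect_equal(d2$max, 3)
  expect_equal(d2$n, 2L)
  # order invariance
  d3 <- descriptive_stats(m2[c(3, 1, 2), ], "labeling_consistency")
  expect_equal(d3, d2)
  expect_error(descriptive_stats(m[0, ], "labeling_consistency"),
               class = "vpp_precondition_error")
})

test_that("spearman matches the brute-force rank formula on tie-free data", {
  set.seed(123)
  for (i in 1:100) {
    n <- sample(4:10, 1)
    x <- sample(1000, n); y <- sample(1000, n)   # tie-free
    r <- spearman_cor(x, y)
    d <- rank(x) - rank(y)
    expect_equal(r$rho, 1 - 6 * sum(d^2) / (n * (n^2 - 1)), tolerance = 1e-12)
  }
})

test_that("spearman agrees with cor.test and handles monotone transforms", {
  set.seed(5)
  x <- rnorm(31); y <- 0.4 * x + rnorm(31)
  r <- spearman_cor(x, y)
  ct <- cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(r$rho, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-10)
  expect_equal(r$df, 29L)

  # invariance under strictly monotone transforms of either variable
  expect_equal(spearman_cor(exp(x), y)$rho, r$rho)
  expect_equal(spearman_cor(x, y^3)$rho, r$rho)

  expect_equal(spearman_cor(1:10, 2 * (1:10))$rho, 1)
  expect_equal(spearman_cor(1:10, 10:1)$rho, -1)
  expect_error(spearman_cor(rep(1, 10), 1:10), class = "vpp_degenerate_error")
  expect_error(spearman_cor(1:3, 3:1), class = "vpp_precondition_error")
})

test_that("correlation suite runs exactly the three planned pairs", {
  set.seed(17)
  m <- data.frame(participant_id = sprintf("P%02d", 1:31),
                  labeling_consistency = runif(31, 0.9, 3.2),
                  log_contrast_distance = rnorm(31, 5.1, 0.2),
                  log_ellipse_area = rnorm(31, 8.9, 0.36),
                  centering_ratio = runif(31, -0.14, 0.25))
  r <- run_correlation_suite(m)
  expect_equal(nrow(r), 3L)
  expect_equal(r$df, rep(29L, 3))
  expect_true(all(grepl("^labeling_consistency ~ ", r$pair)))
  expect_error(run_correlation_suite(m[1:3, ]),
               class = "vpp_precondition_error")
})
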