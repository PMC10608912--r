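test_that("t-statistic implements the signed Welch form", {
  expect_equal(t_statistic(c(10, 11, 12), c(0, 1, 2)), 10 / sqrt(2 / 3),
               tolerance = 1e-12)
  expect_equal(t_statistic(c(1, 2, 3), c(1, 2, 3)), 0)
  # antisymmetric under group swap
  expect_equal(t_statistic(c(0, 1, 2), c(10, 11, 12)),
               -t_statistic(c(10, 11, 12), c(0, 1, 2)))
  expect_error(t_statistic(c(1), c(1, 2)), "at least 2")
  # degenerate: zero variance in both groups
  expect_equal(t_statistic(c(5, 5), c(5, 5)), 0)
  expect_identical(t_statistic(c(5, 5), c(4, 4)), Inf)
})

test_that("t-statistic matches the reference Welch implementation on random groups", {
  withr::with_seed(31, {
    for (i in 1:50) {
      x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
      y <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
      expect_equal(t_statistic(x, y), o_welch(x, y), tolerance = 1e-12)
    }
  })
})

test_that("overlap score counts TP values inside the TN/unknown inner-quartile ranges", {
  # tn = 0..7 has IQR [1.75, 5.25] under the (n-1)*q interpolation rule
  expect_equal(overlap_score(c(1, 3, 6), 0:7, 0:7), 1 / 3, tolerance = 1e-12)
  # disjoint and fully-contained cases
  expect_equal(overlap_score(c(100, 200), 0:7, 0:7), 0)
  expect_equal(overlap_score(c(3, 4), 0:7, 0:7), 1)
  # union of the two groups' IQRs
  expect_equal(overlap_score(c(2, 20), tn_scores = 0:4, unk_scores = 19:23), 1)
  expect_error(overlap_score(numeric(), 0:7, 0:7), "true-positive")
  expect_error(overlap_score(c(1, 2), numeric(), numeric()), "empty")
  expect_message(overlap_score(c(1, 2), 0:7, numeric()), "unknown")
})

test_that("overlap score matches the sort-and-count oracle on random groups", {
  withr::with_seed(55, {
    for (i in 1:30) {
      tp <- rnorm(sample(3:30, 1))
      tn <- rnorm(sample(4:30, 1), 0.5)
      unk <- rnorm(sample(4:30, 1), 0.3)
      expect_equal(suppressMessages(overlap_score(tp, tn, unk)),
                   o_overlap(tp, tn, unk), tolerance = 1e-12)
    }
  })
})

test_that("overlap score is invariant under joint strictly monotone transforms", {
  withr::with_seed(66, {
    tp <- rnorm(20); tn <- rnorm(25, 0.5); unk <- rnorm(15, 0.2)
    base <- overlap_score(tp, tn, unk)
    for (f in list(function(x) 2 * x + 3, exp, function(x) x^3)) {
      expect_equal(overlap_score(f(tp), f(tn), f(unk)), base)
    }
  })
})

test_that("summarize_metric pools annotations for the order statistics", {
  st <- tibble::tibble(
    match_id = paste0("m", 1:5),
    annotation = c("true_positive", "true_positive", "true_negative",
                   "true_negative", "unknown"),
    toy = c(0, 1, 2, 3, 4))
  withr::with_seed(1, {
    s <- suppressMessages(summarize_metric(st, "toy"))
  })
  expect_equal(s$score_min, 0)
  expect_equal(s$score_median, 2)
  expect_equal(s$score_max, 4)
  expect_true(s$score_min <= s$score_median && s$score_median <= s$score_max)
  expect_error(summarize_metric(st, "absent"), "not found")
})

test_that("a perfectly separating metric has a large positive t and zero overlap", {
  st <- tibble::tibble(
    match_id = paste0("m", 1:30),
    annotation = rep(c("true_positive", "true_negative", "unknown"), each = 10),
    sep = c(rnorm(10, 100, 0.1), rnorm(10, 0, 0.1), rnorm(10, 0, 0.1)))
  s <- suppressMessages(summarize_metric(st, "sep"))
  expect_gt(s$t_statistic, 50)
  expect_equal(s$overlap_score, 0)
  # invariant under row permutation
  perm <- withr::with_seed(2, sample(30))
  s2 <- suppressMessages(summarize_metric(st[perm, ], "sep"))
  expect_equal(s2, s)
})

test_that("threshold sweep reports passing fractions per direction", {
  st <- tibble::tibble(
    match_id = paste0("m", 1:5),
    annotation = c("true_positive", "true_positive", "true_positive",
                   "true_negative", "true_negative"),
    cosine_correlation = c(0.9, 0.8, 0.3, 0.6, 0.1),
    euclidean_distance = c(0.1, 0.2, 0.8, 0.5, 0.9))
  sw <- threshold_sweep(st, "cosine_correlation", c(-1, 0.5, 2))
  expect_equal(sw$tp_fraction, c(1, 2 / 3, 0))
  expect_equal(sw$tn_fraction, c(1, 1 / 2, 0))
  # distance metrics pass below the threshold
  swd <- threshold_sweep(st, "euclidean_distance", c(-1, 0.5, 2))
  expect_equal(swd$tp_fraction, c(0, 2 / 3, 1))
  expect_equal(swd$tn_fraction, c(0, 1 / 2, 1))
})

test_that("separation statistics respond to the generator's noise level", {
  # increasing TP noise -> |t| falls and overlap does not fall, for cosine,
  # averaged over three generator seeds; seeds are shared across noise
  # levels (paired design) so only the noise level varies
  sds <- c(0.05, 0.2, 0.4, 0.8, 1.2)
  res <- sapply(seq_along(sds), function(i) {
    per_seed <- sapply(1:3, function(s) {
      st <- tiny_score_table(n_matches = 100, seed = 900 + s,
                             tp_noise_sd = sds[i])
      summ <- suppressMessages(summarize_metric(st, "cosine_correlation"))
      c(t = abs(summ$t_statistic), o = summ$overlap_score)
    })
    rowMeans(per_seed)
  })
  expect_true(all(diff(res["t", ]) < 0))
  expect_true(all(diff(res["o", ]) >= 0))
})
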