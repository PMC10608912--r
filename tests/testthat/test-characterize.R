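make_pipeline_inputs <- function(n_matches = 80, seed = 301, k = 2) {
  st <- tiny_score_table(n_matches = n_matches, seed = seed)
  summ <- summarize_metrics(st, normalization = "sum")
  cc <- suppressWarnings(metric_correlations(st))
  assignment <- suppressWarnings(cluster_metrics(cc, k = k))
  list(score_table = st, summaries = summ, assignment = assignment)
}

test_that("the feature table carries one row per metric with stable encodings", {
  inp <- make_pipeline_inputs()
  ft <- build_feature_table(inp$summaries, assignment = inp$assignment)
  expect_equal(nrow(ft), nrow(inp$assignment))
  expect_true(all(c("family", "direction", "bound_direction", "score_min",
                    "score_median", "score_max", "t_statistic",
                    "overlap_score", "cluster") %in% names(ft)))
  # correlative similarity metrics are bounded on both sides
  expect_equal(as.character(ft$bound_direction[ft$metric == "pearson_correlation"]),
               "both")
  # input order does not matter
  perm <- withr::with_seed(7, sample(nrow(inp$assignment)))
  ft2 <- build_feature_table(inp$summaries[sample(nrow(inp$summaries)), ],
                             assignment = inp$assignment[perm, ])
  expect_equal(ft2, ft)
  expect_error(build_feature_table(inp$summaries[-1, ], assignment = inp$assignment),
               "missing from summaries")
})

test_that("the 75/25 split of 66 metric rows yields 50 train and 16 test", {
  ft <- forced_feature_table(seed = 11)
  parts <- suppressMessages(split_metrics(ft, 0.75, seed = 3))
  expect_equal(nrow(parts$train), 50)
  expect_equal(nrow(parts$test), 16)
  expect_setequal(c(parts$train$metric, parts$test$metric), ft$metric)

  # exact division and determinism
  small <- ft[1:4, ]
  p1 <- suppressWarnings(suppressMessages(split_metrics(small, 0.5, seed = 9)))
  expect_equal(nrow(p1$train), 2)
  expect_equal(nrow(p1$test), 2)
  p2 <- suppressWarnings(suppressMessages(split_metrics(small, 0.5, seed = 9)))
  expect_identical(p1$train$metric, p2$train$metric)
  p3 <- suppressMessages(split_metrics(ft, 0.75, seed = 4))
  expect_false(identical(
    suppressMessages(split_metrics(ft, 0.75, seed = 3))$train$metric,
    p3$train$metric))
})

test_that("tuning is deterministic and a separable predictor gives perfect CV accuracy", {
  ft <- forced_feature_table(seed = 21)
  parts <- suppressMessages(split_metrics(ft, 0.75, seed = 5))
  grid <- data.frame(num_trees = c(300L, 600L), mtry = c(2L, 3L),
                     min_node_size = c(1L, 1L))
  fit1 <- tune_and_fit(parts$train, grid = grid, seed = 17)
  fit2 <- tune_and_fit(parts$train, grid = grid, seed = 17)
  expect_identical(fit1$tuned_parameters, fit2$tuned_parameters)
  expect_identical(fit1$cv_results$mean_cv_accuracy, fit2$cv_results$mean_cv_accuracy)
  # t/overlap determine the response exactly: every grid point separates
  expect_true(all(fit1$cv_results$mean_cv_accuracy == 1))
  # the selected point is the accuracy argmax of the reported CV table
  expect_equal(fit1$tuned_parameters$num_trees,
               grid$num_trees[which.max(fit1$cv_results$mean_cv_accuracy)])
  expect_error(tune_and_fit(parts$train[parts$train$cluster ==
                                          parts$train$cluster[1], ],
                            grid = grid),
               "single cluster")
})

test_that("evaluation reports held-out accuracy and importances scaled to max 100", {
  ft <- forced_feature_table(seed = 31)
  parts <- suppressMessages(split_metrics(ft, 0.75, seed = 5))
  fit <- tune_and_fit(parts$train,
                      grid = data.frame(num_trees = 500L, mtry = 3L,
                                        min_node_size = 1L),
                      seed = 7)
  rep <- evaluate_and_rank(fit, parts$test)
  expect_equal(rep$test_accuracy, 1.0)
  expect_equal(max(rep$importances$scaled), 100)
  expect_true(all(rep$importances$scaled >= 0 & rep$importances$scaled <= 100))
  expect_equal(nrow(rep$predictions), 16)
})

test_that("constructed t/overlap dominance is recovered as the top two importances", {
  for (seed in c(101, 202, 303)) {
    ft <- forced_feature_table(seed = seed)
    parts <- suppressMessages(split_metrics(ft, 0.75, seed = seed))
    fit <- tune_and_fit(parts$train,
                        grid = data.frame(num_trees = 800L, mtry = 3L,
                                          min_node_size = 1L),
                        seed = seed)
    rep <- evaluate_and_rank(fit, parts$test)
    expect_equal(rep$test_accuracy, 1.0, info = paste("seed", seed))
    expect_setequal(rep$importances$predictor[1:2],
                    c("t_statistic", "overlap_score"))
  }
})
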