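# Random-forest characterization of the empirical metric clusters: which
# metric attributes (family, direction, bounds, distributional properties,
# t-statistic, overlap score) predict the cluster a metric lands in?

#' Build the per-metric feature table for cluster characterization
#'
#' One row per metric, combining registry attributes (family, direction,
#' theoretical bound direction), the distributional summaries and separation
#' statistics from [summarize_metrics()], and the empirical cluster from
#' [cluster_metrics()] as the categorical response.
#'
#' @param summaries Tibble from [summarize_metrics()].
#' @param registry Metric registry, defaults to [list_metrics()].
#' @param assignment Tibble from [cluster_metrics()].
#' @return A tibble with columns `metric`, `family`, `direction`,
#'   `bound_direction` (factors), `score_min`, `score_median`, `score_max`,
#'   `t_statistic`, `overlap_score`, and factor response `cluster`. Row
#'   order follows the registry, so the table is invariant to the order of
#'   the inputs.
#' @export
build_feature_table <- function(summaries, registry = list_metrics(), assignment) {
  metrics <- intersect(registry$name, assignment$metric)
  for (m in metrics) {
    if (!m %in% summaries$metric) {
      stop("metric missing from summaries: '", m, "'", call. = FALSE)
    }
  }
  miss <- setdiff(assignment$metric, registry$name)
  if (length(miss)) {
    stop("metric missing from registry: '", miss[1], "'", call. = FALSE)
  }
  base <- registry[registry$name %in% metrics,
                   c("name", "family", "direction", "bound_direction")]
  names(base)[1] <- "metric"
  out <- dplyr::inner_join(base,
                           summaries[, c("metric", "score_min", "score_median",
                                         "score_max", "t_statistic", "overlap_score")],
                           by = "metric")
  out <- dplyr::inner_join(out, assignment, by = "metric")
  if (any(!is.finite(out$t_statistic))) {
    # signed infinities from degenerate groups would break the forest fit
    cap <- max(abs(out$t_statistic[is.finite(out$t_statistic)]), 1)
    out$t_statistic[!is.finite(out$t_statistic)] <-
      sign(out$t_statistic[!is.finite(out$t_statistic)]) * 10 * cap
  }
  out$family <- factor(out$family, levels = sort(unique(registry$family)))
  out$direction <- factor(out$direction, levels = c("distance", "similarity"))
  out$bound_direction <- factor(out$bound_direction,
                                levels = c("left", "right", "both", "none"))
  out$cluster <- factor(out$cluster)
  out[order(match(out$metric, registry$name)), ]
}

round_half_up <- function(x) floor(x + 0.5)

#' Split the metric feature table into training and testing partitions
#'
#' The training size is `round(train_fraction * n)` with half-up rounding,
#' so 66 metrics at 0.75 give the 50-train / 16-test split. Class balance
#' between the partitions is reported via a message; a cluster absent from
#' the training partition triggers a warning (refit with a new seed).
#'
#' @param rows Feature table from [build_feature_table()].
#' @param train_fraction Fraction in (0, 1); default 0.75.
#' @param seed Integer seed controlling the split.
#' @return A list with elements `train` and `test`.
#' @export
split_metrics <- function(rows, train_fraction = 0.75, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n <- nrow(rows)
  n_train <- round_half_up(train_fraction * n)
  idx <- with_seed(seed, sample.int(n, n_train))
  train <- rows[sort(idx), ]
  test <- rows[-sort(idx), ]
  bal_tr <- table(train$cluster) / nrow(train)
  bal_te <- table(test$cluster) / max(nrow(test), 1L)
  message("class balance (train): ",
          paste(sprintf("%s=%.2f", names(bal_tr), bal_tr), collapse = " "),
          " | (test): ",
          paste(sprintf("%s=%.2f", names(bal_te), bal_te), collapse = " "))
  if (any(table(train$cluster) == 0)) {
    warning("a cluster is absent from the training partition; refit with a new seed")
  }
  list(train = train, test = test)
}

#' Default random-forest tuning grid
#'
#' Spans the number of trees, variables sampled per split and minimum node
#' size; it includes the 1395-tree / 3-variable neighbourhood that such
#' models tend to select on metric feature tables.
#'
#' @return A data frame of grid points.
#' @export
default_rf_grid <- function() {
  expand.grid(num_trees = c(500L, 1000L, 1395L, 2000L),
              mtry = c(2L, 3L, 4L),
              min_node_size = c(1L, 5L))
}

rf_formula <- stats::as.formula(
  cluster ~ family + direction + bound_direction +
    score_min + score_median + score_max + t_statistic + overlap_score)

fit_rf <- function(train, num_trees, mtry, min_node_size, seed) {
  ranger::ranger(rf_formula, data = train,
                 num.trees = num_trees,
                 mtry = min(mtry, 8L),
                 min.node.size = min_node_size,
                 importance = "impurity",
                 respect.unordered.factors = "order",
                 seed = seed)
}

#' Tune and fit the cluster-characterization random forest
#'
#' Monte-Carlo cross validation: `cv_repeats` independent random splits of
#' the training rows, each holding out `holdout_fraction` of them, are fit
#' at every grid point; the point with the highest mean holdout accuracy is
#' selected (ties broken by lowest grid index) and refit on the full
#' training set with Gini (impurity) importance. `scheme = "kfold"` swaps
#' the Monte-Carlo splits for `cv_repeats`-fold cross validation.
#'
#' @param train Training rows from [split_metrics()].
#' @param grid Data frame with columns `num_trees`, `mtry`,
#'   `min_node_size`; defaults to [default_rf_grid()].
#' @param cv_repeats Number of Monte-Carlo splits (or folds); default 5.
#' @param holdout_fraction Holdout fraction per split; default 0.10.
#' @param seed Integer seed for the CV splits and the final fit.
#' @param scheme `"mc"` (Monte-Carlo, default) or `"kfold"`.
#' @return A list: `model` (the ranger fit), `tuned_parameters` (one-row
#'   data frame), `cv_results` (mean accuracy per grid point), `cv_seed`.
#' @export
tune_and_fit <- function(train, grid = default_rf_grid(), cv_repeats = 5L,
                         holdout_fraction = 0.10, seed = 1L,
                         scheme = c("mc", "kfold")) {
  scheme <- match.arg(scheme)
  stopifnot(nrow(train) > 0, nrow(grid) > 0)
  if (length(unique(train$cluster)) < 2L) {
    stop("training data contain a single cluster; nothing to classify",
         call. = FALSE)
  }
  n <- nrow(train)
  splits <- with_seed(seed, {
    if (scheme == "mc") {
      n_hold <- max(1L, round_half_up(holdout_fraction * n))
      lapply(seq_len(cv_repeats), function(i) sample.int(n, n_hold))
    } else {
      fold <- sample(rep_len(seq_len(cv_repeats), n))
      lapply(seq_len(cv_repeats), function(i) which(fold == i))
    }
  })
  acc <- vapply(seq_len(nrow(grid)), function(g) {
    mean(vapply(splits, function(hold) {
      fit <- fit_rf(train[-hold, ], grid$num_trees[g], grid$mtry[g],
                    grid$min_node_size[g], seed = seed + g)
      pred <- stats::predict(fit, data = train[hold, ])$predictions
      mean(pred == train$cluster[hold])
    }, numeric(1)))
  }, numeric(1))
  best <- which.max(acc)  # ties -> lowest grid index
  model <- fit_rf(train, grid$num_trees[best], grid$mtry[best],
                  grid$min_node_size[best], seed = seed)
  list(model = model,
       tuned_parameters = data.frame(num_trees = grid$num_trees[best],
                                     mtry = grid$mtry[best],
                                     min_node_size = grid$min_node_size[best]),
       cv_results = cbind(grid, mean_cv_accuracy = acc),
       cv_seed = seed)
}

#' Evaluate the fitted forest and rank variable importances
#'
#' Accuracy on the held-out metric rows plus raw Gini (impurity) importances
#' scaled so the most important predictor sits at exactly 100. Categorical
#' predictors carry one importance per named variable (ranger treats a
#' factor as a single split variable).
#'
#' @param fit List from [tune_and_fit()] (or a bare ranger model).
#' @param test Test rows from [split_metrics()].
#' @return A list of class `model_report`: `test_accuracy`, `importances`
#'   (tibble `predictor`, `raw`, `scaled`), `tuned_parameters`,
#'   `predictions`.
#' @export
evaluate_and_rank <- function(fit, test) {
  model <- if (inherits(fit, "ranger")) fit else fit$model
  stopifnot(nrow(test) > 0)
  pred <- stats::predict(model, data = test)$predictions
  acc <- mean(pred == test$cluster)
  imp <- model$variable.importance
  scaled <- if (max(imp) > 0) 100 * imp / max(imp) else rep(100, length(imp))
  report <- list(
    test_accuracy = acc,
    importances = tibble::tibble(predictor = names(imp),
                                 raw = unname(imp),
                                 scaled = unname(scaled))[order(-scaled), ],
    tuned_parameters = if (is.list(fit) && !is.null(fit$tuned_parameters))
      fit$tuned_parameters else NULL,
    predictions = data.frame(metric = test$metric,
                             truth = test$cluster,
                             predicted = pred)
  )
  class(report) <- "model_report"
  report
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report> test accuracy: ", format(x$test_accuracy), "\n", sep = "")
  cat("top importances:\n")
  print(utils::head(as.data.frame(x$importances), 5))
  invisible(x)
}
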