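# Separation statistics: how well does a metric's score distribution
# distinguish true-positive candidate matches from true-negative / unknown
# ones?

drop_nonfinite <- function(x, what) {
  bad <- !is.finite(x)
  if (any(bad)) {
    message("dropped ", sum(bad), " non-finite ", what, " score(s)")
    x <- x[!bad]
  }
  x
}

#' Welch t-statistic between true-positive and true-negative scores
#'
#' The unpaired two-sided t-statistic in its unequal-variance (Welch) form,
#' `(mean(tp) - mean(tn)) / sqrt(var(tp)/n_tp + var(tn)/n_tn)`. The
#' statistic itself, not a p-value, is the evaluation quantity: it is signed,
#' positive when true positives score higher than true negatives (the
#' expected orientation for similarity-direction metrics, negative for
#' distance-direction ones).
#'
#' @param tp_scores,tn_scores Numeric score vectors; non-finite values are
#'   dropped with a message, and at least 2 finite values per group are
#'   required.
#' @return A single signed statistic. When both groups are constant: 0 if
#'   the means agree, otherwise a signed infinity.
#' @export
#' @examples
#' t_statistic(c(10, 11, 12), c(0, 1, 2))  # 12.2474...
t_statistic <- function(tp_scores, tn_scores) {
  tp <- drop_nonfinite(tp_scores, "true-positive")
  tn <- drop_nonfinite(tn_scores, "true-negative")
  if (length(tp) < 2L || length(tn) < 2L) {
    stop("need at least 2 finite scores in each group", call. = FALSE)
  }
  num <- mean(tp) - mean(tn)
  den <- sqrt(stats::var(tp) / length(tp) + stats::var(tn) / length(tn))
  if (den == 0) {
    if (num == 0) return(0)
    return(sign(num) * Inf)
  }
  num / den
}

iqr_bounds <- function(x) {
  # linear interpolation between order statistics at position (n-1)*q
  stats::quantile(x, probs = c(0.25, 0.75), names = FALSE, type = 7)
}

#' Overlap score of a metric
#'
#' The proportion of true-positive scores lying inside the inner-quartile
#' range (closed interval between the 25th and 75th percentiles) of the
#' true-negative score distribution or of the unknown score distribution,
#' over the total number of true positives. Quartiles use linear
#' interpolation between order statistics (the position `(n-1)*q`
#' convention). `method = "union"` (default) takes the union of the two
#' groups' IQRs; `method = "pooled"` pools true negatives and unknowns into
#' one distribution first.
#'
#' @param tp_scores Non-empty numeric vector of true-positive scores.
#' @param tn_scores,unk_scores True-negative and unknown score vectors; one
#'   may be empty (its interval is then treated as empty, with a message)
#'   but not both.
#' @param method `"union"` or `"pooled"`.
#' @return Proportion in [0, 1].
#' @export
#' @examples
#' overlap_score(c(1, 3, 6), 0:7, 0:7)  # 1/3
overlap_score <- function(tp_scores, tn_scores, unk_scores = numeric(),
                          method = c("union", "pooled")) {
  method <- match.arg(method)
  tp <- drop_nonfinite(tp_scores, "true-positive")
  tn <- drop_nonfinite(tn_scores, "true-negative")
  unk <- drop_nonfinite(unk_scores, "unknown")
  if (length(tp) == 0L) stop("no finite true-positive scores", call. = FALSE)
  if (length(tn) == 0L && length(unk) == 0L) {
    stop("both the true-negative and unknown groups are empty", call. = FALSE)
  }
  inside <- function(x, grp) {
    if (length(grp) == 0L) return(rep(FALSE, length(x)))
    b <- iqr_bounds(grp)
    x >= b[1] & x <= b[2]
  }
  if (method == "pooled") {
    hit <- inside(tp, c(tn, unk))
  } else {
    if (length(tn) == 0L) message("empty true-negative group: its IQR is empty")
    if (length(unk) == 0L) message("empty unknown group: its IQR is empty")
    hit <- inside(tp, tn) | inside(tp, unk)
  }
  mean(hit)
}

#' Summarize one metric's score distribution and separation statistics
#'
#' Computes the per-metric row that feeds clustering and the random-forest
#' feature table: the pooled (all annotations) min / median / max score, the
#' Welch [t_statistic()] between true positives and true negatives, and the
#' [overlap_score()] of true positives against true negatives and unknowns.
#'
#' @param score_table A score table as produced by [score_matches()]:
#'   columns `match_id`, `annotation` (values `true_positive`,
#'   `true_negative`, `unknown`) and one column per metric.
#' @param metric Metric column name.
#' @param normalization Optional tag recorded in the output (e.g. `"sum"`).
#' @param overlap_method Passed to [overlap_score()].
#' @return A one-row tibble: `metric`, `t_statistic`, `overlap_score`,
#'   `score_min`, `score_median`, `score_max`, `normalization`.
#' @export
summarize_metric <- function(score_table, metric, normalization = NA_character_,
                             overlap_method = "union") {
  if (!metric %in% names(score_table)) {
    stop("metric column not found: '", metric, "'", call. = FALSE)
  }
  x <- score_table[[metric]]
  lab <- score_table$annotation
  pooled <- x[is.finite(x)]
  tibble::tibble(
    metric = metric,
    t_statistic = t_statistic(x[lab == "true_positive"], x[lab == "true_negative"]),
    overlap_score = overlap_score(x[lab == "true_positive"],
                                  x[lab == "true_negative"],
                                  x[lab == "unknown"],
                                  method = overlap_method),
    score_min = min(pooled),
    score_median = stats::median(pooled),
    score_max = max(pooled),
    normalization = normalization
  )
}

#' Summarize every metric column of a score table
#'
#' @inheritParams summarize_metric
#' @param metrics Metric columns to summarize; defaults to all registered
#'   metric names present in the table.
#' @return A tibble with one row per metric (see [summarize_metric()]).
#' @export
summarize_metrics <- function(score_table, metrics = NULL,
                              normalization = NA_character_,
                              overlap_method = "union") {
  if (is.null(metrics)) {
    metrics <- intersect(list_metrics()$name, names(score_table))
  }
  dplyr::bind_rows(lapply(metrics, function(m) {
    suppressMessages(summarize_metric(score_table, m, normalization, overlap_method))
  }))
}

#' Sweep an acceptance threshold over a metric
#'
#' For each threshold, the fraction of true-positive and of true-negative
#' matches that pass it. Similarity-direction metrics pass with
#' `score >= threshold`, distance-direction metrics with
#' `score <= threshold`; the direction is looked up in [list_metrics()].
#'
#' @inheritParams summarize_metric
#' @param thresholds Sorted numeric vector of thresholds.
#' @return A tibble `(threshold, tp_fraction, tn_fraction)`; a fraction is
#'   `NaN` when its label group is empty.
#' @export
threshold_sweep <- function(score_table, metric, thresholds) {
  if (!metric %in% names(score_table)) {
    stop("metric column not found: '", metric, "'", call. = FALSE)
  }
  stopifnot(!is.unsorted(thresholds))
  reg <- list_metrics()
  dir <- reg$direction[reg$name == metric]
  if (length(dir) == 0L) stop("metric not in registry: '", metric, "'", call. = FALSE)
  x <- score_table[[metric]]
  lab <- score_table$annotation
  passes <- function(v, thr) {
    v <- v[is.finite(v)]
    if (length(v) == 0L) return(NaN)
    if (dir == "similarity") mean(v >= thr) else mean(v <= thr)
  }
  tibble::tibble(
    threshold = thresholds,
    tp_fraction = vapply(thresholds, function(t) passes(x[lab == "true_positive"], t), numeric(1)),
    tn_fraction = vapply(thresholds, function(t) passes(x[lab == "true_negative"], t), numeric(1))
  )
}
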