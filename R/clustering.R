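# Grouping metrics by the correlation of their scores across candidate
# matches: metric-by-metric Pearson correlation matrix, complete-linkage
# agglomeration, and the family-by-cluster crosstab behind the alluvial view.

#' Pearson correlations between metric score columns
#'
#' Correlates every pair of metric columns across all candidate matches,
#' using pairwise-complete observations when NaN scores are present.
#' Metrics with fewer than 2 finite scores or zero variance are dropped with
#' a warning (a constant column has no defined correlation).
#'
#' @inheritParams summarize_metric
#' @param metrics Metric columns; defaults to all registered metrics present.
#' @return A symmetric correlation matrix with unit diagonal, dimnames the
#'   retained metric names. Cells with fewer than 3 complete pairs are NaN.
#' @export
metric_correlations <- function(score_table, metrics = NULL) {
  if (is.null(metrics)) {
    metrics <- intersect(list_metrics()$name, names(score_table))
  }
  if (nrow(score_table) < 3L) stop("need at least 3 matches", call. = FALSE)
  m <- as.matrix(score_table[, metrics, drop = FALSE])
  m[!is.finite(m)] <- NA_real_
  n_finite <- colSums(!is.na(m))
  sds <- apply(m, 2L, stats::sd, na.rm = TRUE)
  bad <- n_finite < 2L | is.na(sds) | sds == 0
  if (any(bad)) {
    warning("dropped ", sum(bad), " metric(s) with <2 finite scores or zero variance: ",
            paste(metrics[bad], collapse = ", "))
    m <- m[, !bad, drop = FALSE]
  }
  cc <- suppressWarnings(stats::cor(m, use = "pairwise.complete.obs"))
  # too few complete pairs leaves NA; keep as NaN for downstream imputation
  npair <- crossprod(!is.na(m))
  cc[npair < 3L] <- NaN
  diag(cc) <- 1
  cc[is.na(cc) & !is.nan(cc)] <- NaN
  cc
}

#' Cluster metrics by complete-linkage agglomeration
#'
#' Agglomerates metrics on the dissimilarity `d = 1 - r` (default) so that
#' highly correlated metrics are grouped together, or on the Euclidean
#' distance between correlation-matrix rows (`dissimilarity = "rows"`), and
#' cuts the complete-linkage dendrogram into `k` groups. NaN correlations
#' are imputed to 0 with a warning. Cluster ids are relabelled contiguously
#' from 1 in order of first appearance along the input metric order, which
#' makes assignments deterministic for a fixed input.
#'
#' @param corr Correlation matrix from [metric_correlations()].
#' @param k Number of clusters, `1 <= k <= nrow(corr)`.
#' @param dissimilarity `"correlation"` for `1 - r`, `"rows"` for row
#'   distances.
#' @return A tibble `(metric, cluster)` with attributes `k`, `linkage`,
#'   `hclust` (the tree).
#' @export
cluster_metrics <- function(corr, k = 4L,
                            dissimilarity = c("correlation", "rows")) {
  dissimilarity <- match.arg(dissimilarity)
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (k < 1L || k > nrow(corr)) {
    stop("k must be between 1 and ", nrow(corr), call. = FALSE)
  }
  if (any(is.nan(corr))) {
    warning("imputed ", sum(is.nan(corr)), " NaN correlation cell(s) to 0")
    corr[is.nan(corr)] <- 0
  }
  d <- if (dissimilarity == "correlation") {
    stats::as.dist(1 - corr)
  } else {
    stats::dist(corr)
  }
  hc <- stats::hclust(d, method = "complete")
  raw <- stats::cutree(hc, k = k)
  # contiguous ids in order of first appearance
  ids <- match(raw, unique(raw))
  out <- tibble::tibble(metric = rownames(corr), cluster = ids)
  attr(out, "k") <- k
  attr(out, "linkage") <- paste0("complete/", dissimilarity)
  attr(out, "hclust") <- hc
  out
}

#' Cross-tabulate metric families against empirical clusters
#'
#' The counts behind an alluvial family-to-cluster plot: how many metrics of
#' each mathematical family fall in each empirical cluster.
#'
#' @param assignment Tibble from [cluster_metrics()].
#' @param registry Metric registry, defaults to [list_metrics()].
#' @return A tibble `(family, cluster, count)`; counts sum to the number of
#'   clustered metrics.
#' @export
family_cluster_crosstab <- function(assignment, registry = list_metrics()) {
  missing <- setdiff(assignment$metric, registry$name)
  if (length(missing)) {
    stop("metric(s) not in registry: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  joined <- dplyr::inner_join(assignment,
                              registry[, c("name", "family")],
                              by = c(metric = "name"))
  out <- dplyr::count(joined, .data$family, .data$cluster, name = "count")
  dplyr::arrange(out, .data$family, .data$cluster)
}
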