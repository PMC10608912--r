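# Static figures: clustered correlation heatmap, importance bars, and
# per-metric TP/TN/unknown score distributions.

#' Clustered heatmap of metric-metric correlations
#'
#' @param corr Matrix from [metric_correlations()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_correlation_heatmap <- function(corr, path) {
  corr[is.nan(corr)] <- 0
  pheatmap::pheatmap(corr,
                     clustering_method = "complete",
                     clustering_distance_rows = stats::as.dist(1 - corr),
                     clustering_distance_cols = stats::as.dist(1 - corr),
                     fontsize_row = 4, fontsize_col = 4,
                     filename = path, width = 9, height = 9, silent = TRUE)
  invisible(path)
}

#' Bar chart of scaled variable importances
#'
#' @param report A `model_report` from [evaluate_and_rank()].
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
plot_importances <- function(report, path) {
  imp <- report$importances
  p <- ggplot2::ggplot(imp, ggplot2::aes(
    x = .data$scaled, y = stats::reorder(.data$predictor, .data$scaled))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Scaled Gini importance (max = 100)", y = NULL) +
    ggplot2::theme_minimal()
  ggplot2::ggsave(path, p, width = 6, height = 4, dpi = 150)
  invisible(path)
}

#' Per-metric score distribution plots by annotation
#'
#' One density panel per metric showing the true-positive, true-negative
#' and unknown score distributions — the static analogue of browsing each
#' metric's distribution interactively.
#'
#' @param score_table Table from [score_matches()].
#' @param dir Output directory for the PNGs.
#' @param metrics Metric columns to plot; defaults to all present.
#' @return `dir`, invisibly.
#' @export
plot_metric_distributions <- function(score_table, dir, metrics = NULL) {
  if (is.null(metrics)) {
    metrics <- intersect(list_metrics()$name, names(score_table))
  }
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  long <- tidyr::pivot_longer(score_table[, c("annotation", metrics)],
                              dplyr::all_of(metrics),
                              names_to = "metric", values_to = "score")
  long <- long[is.finite(long$score), ]
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$score, fill = .data$annotation)) +
    ggplot2::geom_histogram(bins = 50, alpha = 0.6, position = "identity") +
    ggplot2::facet_wrap(~metric, scales = "free", ncol = 6) +
    ggplot2::theme_minimal(base_size = 7) +
    ggplot2::labs(x = "score", y = "matches")
  ggplot2::ggsave(file.path(dir, "score_distributions.png"), p,
                  width = 14, height = 14, dpi = 120, limitsize = FALSE)
  invisible(dir)
}
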