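# End-to-end orchestration: simulate (or load) candidate matches, score
# them under one or both normalization modes, evaluate each metric, cluster
# the metrics, and characterize the clusters with the random forest.
# Intermediates are plain CSV/JSON so any stage can be inspected, replaced
# or re-run.

#' Pipeline configuration
#'
#' @param generator A [generator_config()] for simulated input, or NULL when
#'   reading spectra from disk.
#' @param input_dir Directory holding `queries.msp`, `references.msp` and
#'   `annotations.csv` (as written by [write_fixture()]); ignored when
#'   `generator` is supplied.
#' @param modes Normalization modes to run, subset of `c("sum", "max")`.
#' @param k Number of metric clusters to cut.
#' @param metric_settings A [metric_config()].
#' @param overlap_method Passed to [summarize_metrics()].
#' @param rf_grid,cv_repeats,holdout_fraction Random-forest tuning settings
#'   (see [tune_and_fit()]).
#' @param train_fraction,split_seed,cv_seed Partitioning and tuning seeds.
#' @param out_dir Output directory.
#' @param make_plots Emit PNG figures (heatmap, importance bars, per-metric
#'   score distributions)?
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            input_dir = NULL,
                            modes = c("sum", "max"),
                            k = 4L,
                            metric_settings = metric_config(),
                            overlap_method = "union",
                            rf_grid = default_rf_grid(),
                            cv_repeats = 5L,
                            holdout_fraction = 0.10,
                            train_fraction = 0.75,
                            split_seed = 1L,
                            cv_seed = 1L,
                            out_dir = tempfile("ssmetrics_run_"),
                            make_plots = TRUE) {
  modes <- match.arg(modes, c("sum", "max"), several.ok = TRUE)
  if (is.null(generator) && is.null(input_dir)) {
    stop("either a generator config or an input directory is required",
         call. = FALSE)
  }
  structure(list(generator = generator, input_dir = input_dir, modes = modes,
                 k = as.integer(k), metric_settings = metric_settings,
                 overlap_method = overlap_method, rf_grid = rf_grid,
                 cv_repeats = cv_repeats, holdout_fraction = holdout_fraction,
                 train_fraction = train_fraction,
                 split_seed = as.integer(split_seed),
                 cv_seed = as.integer(cv_seed),
                 out_dir = out_dir, make_plots = isTRUE(make_plots)),
            class = "pipeline_config")
}

load_matches_from_dir <- function(dir) {
  queries <- read_spectra(file.path(dir, "queries.msp"))
  refs <- read_spectra(file.path(dir, "references.msp"))
  ann <- utils::read.csv(file.path(dir, "annotations.csv"), stringsAsFactors = FALSE)
  qids <- vapply(queries, `[[`, character(1), "id")
  rids <- vapply(refs, `[[`, character(1), "id")
  lapply(seq_len(nrow(ann)), function(i) {
    qi <- match(ann$query_id[i], qids)
    ri <- match(ann$reference_id[i], rids)
    if (is.na(qi) || is.na(ri)) {
      stop("annotation row ", i, " references an unknown spectrum id", call. = FALSE)
    }
    list(match_id = ann$match_id[i], query = queries[[qi]],
         reference = refs[[ri]], annotation = ann$annotation[i])
  })
}

#' Run the full evaluation pipeline
#'
#' For every configured normalization mode: score all candidate matches with
#' the 66 metrics, summarize each metric (t-statistic, overlap, min /
#' median / max), compute the metric correlation matrix, cut `k`
#' complete-linkage clusters, cross-tabulate families against clusters, and
#' fit the tuned random forest predicting cluster membership. All stage
#' outputs are written as CSV/JSON under `out_dir/<mode>/` together with a
#' run manifest (seeds, configuration, content hash); reruns with an
#' identical configuration reproduce identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a named list per mode with elements `score_table`,
#'   `summaries`, `correlations`, `assignment`, `crosstab`, `report`, plus
#'   `matches` and `manifest` at the top level.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  matches <- stage("simulate/load", {
    if (!is.null(config$generator)) {
      lib <- generate_library(config$generator)
      m <- generate_matches(lib, config$generator)
      write_fixture(m, file.path(config$out_dir, "input"), config$generator)
      m
    } else {
      load_matches_from_dir(config$input_dir)
    }
  })
  message("pipeline: ", length(matches), " candidate matches")
  results <- list(matches = matches)
  for (mode in config$modes) {
    mode_dir <- file.path(config$out_dir, mode)
    dir.create(mode_dir, showWarnings = FALSE)
    st <- stage(paste0("score[", mode, "]"),
                score_matches(matches, mode, config$metric_settings))
    utils::write.csv(st, file.path(mode_dir, "score_table.csv"), row.names = FALSE)
    summ <- stage(paste0("evaluate[", mode, "]"),
                  summarize_metrics(st, normalization = mode,
                                    overlap_method = config$overlap_method))
    utils::write.csv(summ, file.path(mode_dir, "evaluation_summary.csv"),
                     row.names = FALSE)
    cc <- stage(paste0("correlate[", mode, "]"), metric_correlations(st))
    utils::write.csv(as.data.frame(cc), file.path(mode_dir, "correlation_matrix.csv"))
    assign_tbl <- stage(paste0("cluster[", mode, "]"),
                        cluster_metrics(cc, k = config$k))
    utils::write.csv(assign_tbl, file.path(mode_dir, "cluster_assignment.csv"),
                     row.names = FALSE)
    xtab <- stage(paste0("crosstab[", mode, "]"),
                  family_cluster_crosstab(assign_tbl))
    utils::write.csv(xtab, file.path(mode_dir, "family_cluster_crosstab.csv"),
                     row.names = FALSE)
    report <- stage(paste0("characterize[", mode, "]"), {
      ft <- build_feature_table(summ, assignment = assign_tbl)
      parts <- suppressMessages(
        split_metrics(ft, config$train_fraction, config$split_seed))
      fit <- tune_and_fit(parts$train, grid = config$rf_grid,
                          cv_repeats = config$cv_repeats,
                          holdout_fraction = config$holdout_fraction,
                          seed = config$cv_seed)
      evaluate_and_rank(fit, parts$test)
    })
    jsonlite::write_json(
      list(test_accuracy = report$test_accuracy,
           tuned_parameters = report$tuned_parameters,
           importances = report$importances,
           split_seed = config$split_seed, cv_seed = config$cv_seed),
      file.path(mode_dir, "model_report.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows")
    if (config$make_plots) {
      try_plot <- function(expr) tryCatch(expr, error = function(e)
        warning("plotting failed: ", conditionMessage(e)))
      try_plot(plot_correlation_heatmap(cc, file.path(mode_dir, "correlation_heatmap.png")))
      try_plot(plot_importances(report, file.path(mode_dir, "importances.png")))
      try_plot(plot_metric_distributions(st, file.path(mode_dir, "distributions")))
    }
    results[[mode]] <- list(score_table = st, summaries = summ,
                            correlations = cc, assignment = assign_tbl,
                            crosstab = xtab, report = report)
  }
  manifest <- list(
    n_matches = length(matches),
    modes = config$modes,
    k = config$k,
    seeds = list(generator = if (!is.null(config$generator)) config$generator$seed,
                 split = config$split_seed, cv = config$cv_seed),
    config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("ssmetrics")))
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  results$manifest <- manifest
  invisible(results)
}
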