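# Metric implementations. Every function takes the aligned abundance vectors
# P (query) and Q (reference) on the shared m/z grid, plus the numeric policy
# in `cfg`, and returns a single score. All 66 are coded directly from their
# defining formulas; the registry in metrics-registry.R carries their
# metadata.

# x/y with the 0/0 -> 0 convention and an additive eps on zero denominators.
div0 <- function(num, den, eps) {
  out <- num / (den + eps * (den == 0))
  out[num == 0 & den == 0] <- 0
  out
}

# log(num/den) with additive eps on zero arguments (callers multiply by a
# factor that is 0 whenever the term must vanish, so the result stays finite).
logr <- function(num, den, eps) {
  log((num + eps * (num == 0)) / (den + eps * (den == 0)))
}

logx <- function(x, eps) log(x + eps * (x == 0))

safe_cor <- function(x, y, method = "pearson") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NaN)
  stats::cor(x, y, method = method)
}

metric_functions <- function() {
  list(
    ## Lp ---------------------------------------------------------------
    manhattan_distance   = function(mz, P, Q, cfg) sum(abs(P - Q)),
    euclidean_distance   = function(mz, P, Q, cfg) sqrt(sum((P - Q)^2)),
    minkowski_3_distance = function(mz, P, Q, cfg) sum(abs(P - Q)^3)^(1/3),
    chebyshev_distance   = function(mz, P, Q, cfg) max(abs(P - Q)),
    ## L1 ---------------------------------------------------------------
    sorensen_distance    = function(mz, P, Q, cfg) sum(abs(P - Q)) / sum(P + Q),
    gower_distance       = function(mz, P, Q, cfg) mean(abs(P - Q)),
    soergel_distance     = function(mz, P, Q, cfg) sum(abs(P - Q)) / sum(pmax(P, Q)),
    kulczynski_1_distance = function(mz, P, Q, cfg)
      div0(sum(abs(P - Q)), sum(pmin(P, Q)), cfg$eps),
    canberra_distance    = function(mz, P, Q, cfg)
      sum(div0(abs(P - Q), P + Q, cfg$eps)),
    canberra_metric      = function(mz, P, Q, cfg)
      sum(div0(abs(P - Q), P + Q, cfg$eps)) / sum((P + Q) > 0),
    lorentzian_distance  = function(mz, P, Q, cfg) sum(log1p(abs(P - Q))),
    whittaker_index_of_association_distance = function(mz, P, Q, cfg)
      0.5 * sum(abs(P / sum(P) - Q / sum(Q))),
    ## Intersection ------------------------------------------------------
    intersection_similarity = function(mz, P, Q, cfg) sum(pmin(P, Q)),
    intersection_distance   = function(mz, P, Q, cfg) 0.5 * sum(abs(P - Q)),
    wave_hedges_distance    = function(mz, P, Q, cfg)
      sum(div0(abs(P - Q), pmax(P, Q), cfg$eps)),
    czekanowski_similarity  = function(mz, P, Q, cfg) 2 * sum(pmin(P, Q)) / sum(P + Q),
    czekanowski_distance    = function(mz, P, Q, cfg) sum(abs(P - Q)) / sum(P + Q),
    motyka_similarity       = function(mz, P, Q, cfg) sum(pmin(P, Q)) / sum(P + Q),
    motyka_distance         = function(mz, P, Q, cfg) sum(pmax(P, Q)) / sum(P + Q),
    kulczynski_2_similarity = function(mz, P, Q, cfg)
      div0(sum(pmin(P, Q)), sum(abs(P - Q)), cfg$eps),
    ruzicka_similarity      = function(mz, P, Q, cfg) sum(pmin(P, Q)) / sum(pmax(P, Q)),
    tanimoto_distance       = function(mz, P, Q, cfg)
      sum(pmax(P, Q) - pmin(P, Q)) / sum(pmax(P, Q)),
    ## Inner Product -----------------------------------------------------
    inner_product_similarity = function(mz, P, Q, cfg) sum(P * Q),
    harmonic_mean_similarity = function(mz, P, Q, cfg)
      2 * sum(div0(P * Q, P + Q, cfg$eps)),
    cosine_correlation = function(mz, P, Q, cfg)
      sum(P * Q) / (sqrt(sum(P^2)) * sqrt(sum(Q^2))),
    kumar_hassebrook_similarity = function(mz, P, Q, cfg)
      sum(P * Q) / (sum(P^2) + sum(Q^2) - sum(P * Q)),
    jaccard_distance = function(mz, P, Q, cfg)
      1 - sum(P * Q) / (sum(P^2) + sum(Q^2) - sum(P * Q)),
    dice_similarity = function(mz, P, Q, cfg)
      2 * sum(P * Q) / (sum(P^2) + sum(Q^2)),
    dice_distance = function(mz, P, Q, cfg)
      1 - 2 * sum(P * Q) / (sum(P^2) + sum(Q^2)),
    weighted_cosine_correlation = function(mz, P, Q, cfg) {
      wp <- mz^cfg$wc_mz_power * P^cfg$wc_int_power
      wq <- mz^cfg$wc_mz_power * Q^cfg$wc_int_power
      sum(wp * wq) / (sqrt(sum(wp^2)) * sqrt(sum(wq^2)))
    },
    stein_scott_similarity = function(mz, P, Q, cfg)
      composite_similarity(mz, P, Q, cfg$ss_int_power, cfg$ss_mz_power, cfg),
    stein_scott_similarity_nist = function(mz, P, Q, cfg)
      composite_similarity(mz, P, Q, cfg$nist_int_power, cfg$nist_mz_power, cfg),
    dft_correlation = function(mz, P, Q, cfg)
      transform_composite(mz, P, Q, "dft", cfg),
    dwt_correlation = function(mz, P, Q, cfg)
      transform_composite(mz, P, Q, "dwt", cfg),
    ## Fidelity ----------------------------------------------------------
    fidelity_similarity  = function(mz, P, Q, cfg) sum(sqrt(P * Q)),
    bhattacharyya_distance = function(mz, P, Q, cfg) {
      f <- sum(sqrt(P * Q))
      -log(f + cfg$eps * (f == 0))
    },
    hellinger_distance   = function(mz, P, Q, cfg)
      sqrt(2 * sum((sqrt(P) - sqrt(Q))^2)),
    matusita_distance    = function(mz, P, Q, cfg)
      sqrt(sum((sqrt(P) - sqrt(Q))^2)),
    squared_chord_distance = function(mz, P, Q, cfg)
      sum((sqrt(P) - sqrt(Q))^2),
    squared_chord_similarity = function(mz, P, Q, cfg)
      2 * sum(sqrt(P * Q)) - 1,
    ## Chi Squared --------------------------------------------------------
    squared_euclidean_distance = function(mz, P, Q, cfg) sum((P - Q)^2),
    pearson_chi_squared_distance = function(mz, P, Q, cfg)
      sum(div0((P - Q)^2, Q, cfg$eps)),
    neyman_chi_squared_distance = function(mz, P, Q, cfg)
      sum(div0((P - Q)^2, P, cfg$eps)),
    squared_chi_squared_distance = function(mz, P, Q, cfg)
      sum(div0((P - Q)^2, P + Q, cfg$eps)),
    probabilistic_symmetric_chi_squared_distance = function(mz, P, Q, cfg)
      2 * sum(div0((P - Q)^2, P + Q, cfg$eps)),
    divergence_distance = function(mz, P, Q, cfg)
      2 * sum(div0((P - Q)^2, (P + Q)^2, cfg$eps)),
    clark_distance = function(mz, P, Q, cfg)
      sqrt(sum(div0(abs(P - Q), P + Q, cfg$eps)^2)),
    additive_symmetric_chi_squared_distance = function(mz, P, Q, cfg)
      sum(div0((P - Q)^2 * (P + Q), P * Q, cfg$eps)),
    ## Shannon's Entropy --------------------------------------------------
    kullback_leibler_divergence = function(mz, P, Q, cfg)
      sum(P * logr(P, Q, cfg$eps)),
    jeffreys_divergence = function(mz, P, Q, cfg)
      sum((P - Q) * logr(P, Q, cfg$eps)),
    k_divergence = function(mz, P, Q, cfg)
      sum(P * logr(2 * P, P + Q, cfg$eps)),
    topsoe_distance = function(mz, P, Q, cfg)
      sum(P * logr(2 * P, P + Q, cfg$eps) + Q * logr(2 * Q, P + Q, cfg$eps)),
    jensen_shannon_divergence = function(mz, P, Q, cfg)
      0.5 * sum(P * logr(2 * P, P + Q, cfg$eps) + Q * logr(2 * Q, P + Q, cfg$eps)),
    jensen_difference_distance = function(mz, P, Q, cfg) {
      s <- (P + Q) / 2
      sum((P * logx(P, cfg$eps) + Q * logx(Q, cfg$eps)) / 2 - s * logx(s, cfg$eps))
    },
    kumar_johnson_divergence = function(mz, P, Q, cfg)
      sum(div0((P^2 - Q^2)^2, 2 * (P * Q)^1.5, cfg$eps)),
    ## Vicis Wave Hedges ---------------------------------------------------
    vicis_wave_hedges_distance = function(mz, P, Q, cfg)
      sum(div0(abs(P - Q), pmin(P, Q), cfg$eps)),
    vicis_symmetric_chi_squared_1_distance = function(mz, P, Q, cfg)
      sum(div0((P - Q)^2, pmin(P, Q)^2, cfg$eps)),
    vicis_symmetric_chi_squared_2_distance = function(mz, P, Q, cfg)
      sum(div0((P - Q)^2, pmin(P, Q), cfg$eps)),
    vicis_symmetric_chi_squared_3_distance = function(mz, P, Q, cfg)
      sum(div0((P - Q)^2, pmax(P, Q), cfg$eps)),
    max_symmetric_chi_squared_distance = function(mz, P, Q, cfg)
      max(sum(div0((P - Q)^2, P, cfg$eps)), sum(div0((P - Q)^2, Q, cfg$eps))),
    min_symmetric_chi_squared_distance = function(mz, P, Q, cfg)
      min(sum(div0((P - Q)^2, P, cfg$eps)), sum(div0((P - Q)^2, Q, cfg$eps))),
    ## Combined ------------------------------------------------------------
    average_l1_linf_distance = function(mz, P, Q, cfg)
      (sum(abs(P - Q)) + max(abs(P - Q))) / 2,
    taneja_divergence = function(mz, P, Q, cfg)
      sum(((P + Q) / 2) * logr(P + Q, 2 * sqrt(P * Q), cfg$eps)),
    ## Correlative ---------------------------------------------------------
    pearson_correlation = function(mz, P, Q, cfg) safe_cor(P, Q, "pearson"),
    spearman_correlation = function(mz, P, Q, cfg) safe_cor(P, Q, "spearman"),
    kendall_tau_correlation = function(mz, P, Q, cfg) safe_cor(P, Q, "kendall")
  )
}

.metric_env <- new.env(parent = emptyenv())

get_metric_functions <- function() {
  if (is.null(.metric_env$funs)) .metric_env$funs <- metric_functions()
  .metric_env$funs
}

clamp_score <- function(v, cap) {
  if (is.nan(v)) return(NaN)
  if (!is.finite(v) || abs(v) > cap) return(sign(v) * cap)
  v
}

#' Compute one similarity/distance metric on an aligned spectrum pair
#'
#' @param pair An [align_spectra()] result.
#' @param metric Name of a registered metric (see [list_metrics()]).
#' @param config A [metric_config()].
#' @return A single numeric score (possibly `NaN` when the metric is
#'   undefined for the pair, e.g. a zero-variance correlation); non-finite
#'   and overflowing values are clamped to `config$cap` in magnitude.
#' @export
#' @examples
#' q <- spectrum("q", c(70, 85, 99), c(1, 2, 2))
#' r <- spectrum("r", c(70, 85, 99), c(2, 1, 2))
#' compute_score(align_spectra(q, r), "cosine_correlation")
compute_score <- function(pair, metric, config = metric_config()) {
  stopifnot(inherits(pair, "aligned_pair"))
  funs <- get_metric_functions()
  f <- funs[[metric]]
  if (is.null(f)) stop("unknown metric: '", metric, "'", call. = FALSE)
  clamp_score(f(pair$mz, pair$P, pair$Q, config), config$cap)
}

#' Compute all 66 registered metrics on an aligned pair
#'
#' Equivalent to calling [compute_score()] for every entry of
#' [list_metrics()], in registry order. A `NaN` from one metric does not
#' abort the batch.
#'
#' @inheritParams compute_score
#' @return A named numeric vector of length 66.
#' @export
compute_all_scores <- function(pair, config = metric_config()) {
  stopifnot(inherits(pair, "aligned_pair"))
  funs <- get_metric_functions()
  mz <- pair$mz; P <- pair$P; Q <- pair$Q
  cap <- config$cap
  vapply(funs, function(f) clamp_score(f(mz, P, Q, config), cap), numeric(1))
}
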