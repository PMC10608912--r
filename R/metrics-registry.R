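# Registry of the 66 spectral similarity / distance metrics.
#
# Families follow the Cha taxonomy of distance measures between probability
# vectors, which is how the field groups these scores: Chi Squared,
# Correlative, Fidelity, Inner Product, Intersection, L1, Lp, Shannon's
# Entropy, Vicis Wave Hedges, and Combined. Theoretical bounds are declared
# under the sum (probability) scaling convention; `identity` is the value a
# metric takes on two identical sum-scaled spectra where the formula forces
# one (NA where the value is data-dependent or diverges).

metric_registry_table <- function() {
  r <- function(name, family, direction, lower, upper, symmetric, identity) {
    tibble::tibble(name = name, family = family, direction = direction,
                   lower = lower, upper = upper, symmetric = symmetric,
                   identity = identity)
  }
  dplyr::bind_rows(
    # -- Lp (Minkowski) family -------------------------------------------
    r("manhattan_distance",            "Lp", "distance", 0, 2,        TRUE, 0),
    r("euclidean_distance",            "Lp", "distance", 0, sqrt(2),  TRUE, 0),
    r("minkowski_3_distance",          "Lp", "distance", 0, 2^(1/3),  TRUE, 0),
    r("chebyshev_distance",            "Lp", "distance", 0, 1,        TRUE, 0),
    # -- L1 family --------------------------------------------------------
    r("sorensen_distance",             "L1", "distance", 0, 1,   TRUE, 0),
    r("gower_distance",                "L1", "distance", 0, Inf, TRUE, 0),
    r("soergel_distance",              "L1", "distance", 0, 1,   TRUE, 0),
    r("kulczynski_1_distance",         "L1", "distance", 0, Inf, TRUE, 0),
    r("canberra_distance",             "L1", "distance", 0, Inf, TRUE, 0),
    r("canberra_metric",               "L1", "distance", 0, 1,   TRUE, 0),
    r("lorentzian_distance",           "L1", "distance", 0, Inf, TRUE, 0),
    r("whittaker_index_of_association_distance",
                                       "L1", "distance", 0, 1,   TRUE, 0),
    # -- Intersection family ---------------------------------------------
    r("intersection_similarity",       "Intersection", "similarity", 0, 1,   TRUE, 1),
    r("intersection_distance",         "Intersection", "distance",   0, 1,   TRUE, 0),
    r("wave_hedges_distance",          "Intersection", "distance",   0, Inf, TRUE, 0),
    r("czekanowski_similarity",        "Intersection", "similarity", 0, 1,   TRUE, 1),
    r("czekanowski_distance",          "Intersection", "distance",   0, 1,   TRUE, 0),
    r("motyka_similarity",             "Intersection", "similarity", 0, 0.5, TRUE, 0.5),
    r("motyka_distance",               "Intersection", "distance",   0.5, 1, TRUE, 0.5),
    r("kulczynski_2_similarity",       "Intersection", "similarity", 0, Inf, TRUE, NA),
    r("ruzicka_similarity",            "Intersection", "similarity", 0, 1,   TRUE, 1),
    r("tanimoto_distance",             "Intersection", "distance",   0, 1,   TRUE, 0),
    # -- Inner Product family --------------------------------------------
    r("inner_product_similarity",      "Inner Product", "similarity", 0, 1, TRUE, NA),
    r("harmonic_mean_similarity",      "Inner Product", "similarity", 0, 1, TRUE, 1),
    r("cosine_correlation",            "Inner Product", "similarity", 0, 1, TRUE, 1),
    r("kumar_hassebrook_similarity",   "Inner Product", "similarity", 0, 1, TRUE, 1),
    r("jaccard_distance",              "Inner Product", "distance",   0, 1, TRUE, 0),
    r("dice_similarity",               "Inner Product", "similarity", 0, 1, TRUE, 1),
    r("dice_distance",                 "Inner Product", "distance",   0, 1, TRUE, 0),
    r("weighted_cosine_correlation",   "Inner Product", "similarity", 0, 1, TRUE, 1),
    r("stein_scott_similarity",        "Inner Product", "similarity", 0, 1, FALSE, 1),
    r("stein_scott_similarity_nist",   "Inner Product", "similarity", 0, 1, FALSE, 1),
    r("dft_correlation",               "Inner Product", "similarity", -1, 1, FALSE, 1),
    r("dwt_correlation",               "Inner Product", "similarity", -1, 1, FALSE, 1),
    # -- Fidelity family --------------------------------------------------
    r("fidelity_similarity",           "Fidelity", "similarity", 0, 1,       TRUE, 1),
    r("bhattacharyya_distance",        "Fidelity", "distance",   0, Inf,     TRUE, 0),
    r("hellinger_distance",            "Fidelity", "distance",   0, 2,       TRUE, 0),
    r("matusita_distance",             "Fidelity", "distance",   0, sqrt(2), TRUE, 0),
    r("squared_chord_distance",        "Fidelity", "distance",   0, 2,       TRUE, 0),
    r("squared_chord_similarity",      "Fidelity", "similarity", -1, 1,      TRUE, 1),
    # -- Chi Squared family ----------------------------------------------
    r("squared_euclidean_distance",    "Chi Squared", "distance", 0, 2,   TRUE,  0),
    r("pearson_chi_squared_distance",  "Chi Squared", "distance", 0, Inf, FALSE, 0),
    r("neyman_chi_squared_distance",   "Chi Squared", "distance", 0, Inf, FALSE, 0),
    r("squared_chi_squared_distance",  "Chi Squared", "distance", 0, 2,   TRUE,  0),
    r("probabilistic_symmetric_chi_squared_distance",
                                       "Chi Squared", "distance", 0, 4,   TRUE,  0),
    r("divergence_distance",           "Chi Squared", "distance", 0, Inf, TRUE,  0),
    r("clark_distance",                "Chi Squared", "distance", 0, Inf, TRUE,  0),
    r("additive_symmetric_chi_squared_distance",
                                       "Chi Squared", "distance", 0, Inf, TRUE,  0),
    # -- Shannon's Entropy family ----------------------------------------
    r("kullback_leibler_divergence",   "Shannon's Entropy", "distance", 0, Inf,      FALSE, 0),
    r("jeffreys_divergence",           "Shannon's Entropy", "distance", 0, Inf,      TRUE,  0),
    r("k_divergence",                  "Shannon's Entropy", "distance", 0, log(2),   FALSE, 0),
    r("topsoe_distance",               "Shannon's Entropy", "distance", 0, 2*log(2), TRUE,  0),
    r("jensen_shannon_divergence",     "Shannon's Entropy", "distance", 0, log(2),   TRUE,  0),
    r("jensen_difference_distance",    "Shannon's Entropy", "distance", 0, log(2),   TRUE,  0),
    r("kumar_johnson_divergence",      "Shannon's Entropy", "distance", 0, Inf,      TRUE,  0),
    # -- Vicis Wave Hedges family ----------------------------------------
    r("vicis_wave_hedges_distance",               "Vicis Wave Hedges", "distance", 0, Inf, TRUE, 0),
    r("vicis_symmetric_chi_squared_1_distance",   "Vicis Wave Hedges", "distance", 0, Inf, TRUE, 0),
    r("vicis_symmetric_chi_squared_2_distance",   "Vicis Wave Hedges", "distance", 0, Inf, TRUE, 0),
    r("vicis_symmetric_chi_squared_3_distance",   "Vicis Wave Hedges", "distance", 0, Inf, TRUE, 0),
    r("max_symmetric_chi_squared_distance",       "Vicis Wave Hedges", "distance", 0, Inf, TRUE, 0),
    r("min_symmetric_chi_squared_distance",       "Vicis Wave Hedges", "distance", 0, Inf, TRUE, 0),
    # -- Combined ---------------------------------------------------------
    r("average_l1_linf_distance",      "Combined", "distance", 0, 1.5, TRUE, 0),
    r("taneja_divergence",             "Combined", "distance", 0, Inf, TRUE, 0),
    # -- Correlative family ----------------------------------------------
    r("pearson_correlation",           "Correlative", "similarity", -1, 1, TRUE, 1),
    r("spearman_correlation",          "Correlative", "similarity", -1, 1, TRUE, 1),
    r("kendall_tau_correlation",       "Correlative", "similarity", -1, 1, TRUE, 1)
  )
}

.registry_cache <- new.env(parent = emptyenv())

#' List the registered spectral similarity metrics
#'
#' Returns the registry of all 66 metrics in a stable order, one row per
#' metric, with its family (one of ten), direction (`"similarity"`: higher
#' means more alike; `"distance"`: lower means more alike), declared
#' theoretical bounds under sum scaling, a derived `bound_direction`
#' (`left`, `right`, `both`, `none`), whether the metric is symmetric in its
#' two arguments, and the score forced on identical spectra (`identity`,
#' NA where data-dependent). Direction is metadata only: no score is negated
#' onto a common orientation.
#'
#' @return A tibble with 66 rows.
#' @export
#' @examples
#' nrow(list_metrics())          # 66
#' length(unique(list_metrics()$family))  # 10
list_metrics <- function() {
  if (is.null(.registry_cache$tbl)) {
    tbl <- metric_registry_table()
    tbl$bound_direction <- ifelse(
      is.finite(tbl$lower) & is.finite(tbl$upper), "both",
      ifelse(is.finite(tbl$lower), "left",
             ifelse(is.finite(tbl$upper), "right", "none")))
    .registry_cache$tbl <- tbl
  }
  .registry_cache$tbl
}

#' Metric computation settings
#'
#' Collects the numerical policy shared by all metric implementations.
#'
#' Zero handling on the fully joined grid: terms of the form 0/0 and
#' 0*log(0) are defined as 0; denominators and log arguments that must be
#' strictly positive receive an additive `eps` when they are exactly zero;
#' scores whose magnitude still exceeds `cap` (left-bounded distances on
#' near-disjoint support) are clamped to `sign(x) * cap`.
#'
#' @param eps Additive epsilon for zero denominators / log arguments.
#' @param cap Magnitude cap applied to non-finite or overflowing scores.
#' @param ss_int_power,ss_mz_power Intensity and m/z weighting exponents for
#'   the composite Stein-Scott similarity (0.6 and 3, the classic optimum).
#' @param nist_int_power,nist_mz_power Exponents for the NIST variant of the
#'   composite (0.53 and 1.3, the NIST search convention).
#' @param wc_int_power,wc_mz_power Exponents for the weighted cosine
#'   correlation and for the cosine term of the transform composites.
#' @param transform_pad `"pow2"`: zero-pad vectors to the next power of two
#'   before the DFT/DWT.
#' @param transform_keep Fraction of low-order transform coefficients kept
#'   for the correlation term.
#' @param wavelet Wavelet basis for [transform_correlation()]; only
#'   `"haar"` is implemented.
#' @return A named list of class `metric_config`.
#' @export
metric_config <- function(eps = 1e-13, cap = 1e12,
                          ss_int_power = 0.6, ss_mz_power = 3,
                          nist_int_power = 0.53, nist_mz_power = 1.3,
                          wc_int_power = 0.5, wc_mz_power = 1.3,
                          transform_pad = "pow2", transform_keep = 0.5,
                          wavelet = "haar") {
  stopifnot(eps > 0, cap > 0, transform_keep > 0, transform_keep <= 1)
  wavelet <- match.arg(wavelet, "haar")
  structure(list(eps = eps, cap = cap,
                 ss_int_power = ss_int_power, ss_mz_power = ss_mz_power,
                 nist_int_power = nist_int_power, nist_mz_power = nist_mz_power,
                 wc_int_power = wc_int_power, wc_mz_power = wc_mz_power,
                 transform_pad = transform_pad, transform_keep = transform_keep,
                 wavelet = wavelet),
            class = "metric_config")
}
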