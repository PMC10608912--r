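# Seeded generator of annotated candidate-match data with the statistical
# structure library search produces: a reference library of unit-resolution
# EI spectra, true-positive queries derived from their paired reference
# under multiplicative intensity noise / peak dropout / contaminant peaks,
# true-negative queries derived from a different library spectrum, and
# "unknown" queries blended from the paired reference and a decoy.

#' Configuration for the synthetic candidate-match generator
#'
#' Defaults emulate a unit-resolution single-quadrupole GC-MS experiment:
#' integer fragment m/z on the 50--550 Da acquisition window, 20--40
#' significant fragment peaks per compound with exponentially distributed
#' intensities (a few dominant fragments, a long tail of minor ones),
#' log-normal multiplicative intensity noise with log-scale SD 0.25 (about
#' 25% replicate variability), 5% per-peak dropout, on average one spurious
#' (contaminant) peak per query, and unknowns blended with 30% weight on the
#' true reference. The shipped study scale is 200 reference compounds and
#' 5000 candidate matches at 40/40/20 TP/TN/unknown proportions.
#'
#' @param n_reference_spectra Number of library compounds.
#' @param peaks_per_spectrum Integer range (length 2) of peaks per spectrum.
#' @param mz_window Acquisition m/z window (Da).
#' @param intensity_rate Rate of the exponential base-intensity law.
#' @param tp_noise_sd Log-scale SD of the multiplicative intensity noise.
#' @param dropout_prob Per-peak removal probability for queries.
#' @param contaminant_rate Poisson mean of spurious peaks per query.
#' @param contaminant_scale Contaminant intensities are drawn from the base
#'   law and multiplied by this factor (contaminants are minor peaks).
#' @param unknown_blend_weight Mixing fraction of the true reference in an
#'   unknown query's template (the rest comes from a decoy spectrum).
#' @param n_matches Number of candidate matches to generate.
#' @param label_proportions Named numeric `(tp, tn, unknown)` summing to 1.
#' @param seed Integer seed; the whole dataset is a pure function of the
#'   configuration.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_reference_spectra = 200L,
                             peaks_per_spectrum = c(20L, 40L),
                             mz_window = c(50, 550),
                             intensity_rate = 1,
                             tp_noise_sd = 0.25,
                             dropout_prob = 0.05,
                             contaminant_rate = 1,
                             contaminant_scale = 0.1,
                             unknown_blend_weight = 0.3,
                             n_matches = 5000L,
                             label_proportions = c(tp = 0.4, tn = 0.4, unknown = 0.2),
                             seed = 1L) {
  stopifnot(n_reference_spectra >= 1L,
            length(peaks_per_spectrum) == 2L,
            peaks_per_spectrum[1] >= 1L,
            peaks_per_spectrum[1] <= peaks_per_spectrum[2],
            length(mz_window) == 2L, mz_window[1] < mz_window[2],
            tp_noise_sd >= 0, dropout_prob >= 0, dropout_prob <= 1,
            contaminant_rate >= 0,
            unknown_blend_weight >= 0, unknown_blend_weight <= 1,
            n_matches >= 1L,
            abs(sum(label_proportions) - 1) < 1e-9,
            all(label_proportions >= 0))
  if (peaks_per_spectrum[2] > diff(mz_window) + 1) {
    stop("peaks_per_spectrum exceeds the number of integer m/z values in the window",
         call. = FALSE)
  }
  structure(list(n_reference_spectra = as.integer(n_reference_spectra),
                 peaks_per_spectrum = as.integer(peaks_per_spectrum),
                 mz_window = mz_window,
                 intensity_rate = intensity_rate,
                 tp_noise_sd = tp_noise_sd,
                 dropout_prob = dropout_prob,
                 contaminant_rate = contaminant_rate,
                 contaminant_scale = contaminant_scale,
                 unknown_blend_weight = unknown_blend_weight,
                 n_matches = as.integer(n_matches),
                 label_proportions = label_proportions,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a synthetic reference library
#'
#' Integer m/z values sampled without replacement from the acquisition
#' window; intensities from the configured exponential law, scaled to
#' maximum 100 (library convention). Deterministic for a fixed seed.
#'
#' @param config A [generator_config()].
#' @return A list of `n_reference_spectra` [spectrum()] objects.
#' @export
generate_library <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  mz_values <- seq(ceiling(config$mz_window[1]), floor(config$mz_window[2]))
  with_seed(config$seed, {
    lapply(seq_len(config$n_reference_spectra), function(i) {
      n_pk <- sample(config$peaks_per_spectrum[1]:config$peaks_per_spectrum[2], 1L)
      mz <- sort(sample(mz_values, n_pk))
      intensity <- stats::rexp(n_pk, rate = config$intensity_rate)
      intensity <- 100 * intensity / max(intensity)
      spectrum(sprintf("REF_%04d", i), mz, intensity,
               mz_window = config$mz_window)
    })
  })
}

# Corrupt a template spectrum the way a measured query differs from its
# library entry: multiplicative log-normal noise, per-peak dropout (never
# removing every peak), and Poisson-many minor contaminant peaks at m/z
# values the template lacks.
perturb_spectrum <- function(template, id, config) {
  mz <- template$mz
  intensity <- template$intensity
  if (config$tp_noise_sd > 0) {
    intensity <- intensity * exp(stats::rnorm(length(intensity), 0, config$tp_noise_sd))
  }
  if (config$dropout_prob > 0 && length(mz) > 1L) {
    drop <- stats::runif(length(mz)) < config$dropout_prob
    if (all(drop)) drop[which.max(intensity)] <- FALSE
    mz <- mz[!drop]
    intensity <- intensity[!drop]
  }
  if (config$contaminant_rate > 0) {
    n_cont <- stats::rpois(1L, config$contaminant_rate)
    if (n_cont > 0L) {
      free <- setdiff(seq(ceiling(config$mz_window[1]), floor(config$mz_window[2])), mz)
      n_cont <- min(n_cont, length(free))
      cmz <- sample(free, n_cont)
      cint <- stats::rexp(n_cont, rate = config$intensity_rate) *
        config$contaminant_scale * max(intensity)
      mz <- c(mz, cmz)
      intensity <- c(intensity, cint)
    }
  }
  spectrum(id, mz, intensity, mz_window = config$mz_window)
}

# Abundance-space blend of two spectra (each sum-scaled first).
blend_spectra <- function(a, b, weight_a, id) {
  a <- normalize_spectrum(a, "sum")
  b <- normalize_spectrum(b, "sum")
  grid <- sort(unique(c(a$mz, b$mz)))
  v <- numeric(length(grid))
  v[match(a$mz, grid)] <- v[match(a$mz, grid)] + weight_a * a$intensity
  v[match(b$mz, grid)] <- v[match(b$mz, grid)] + (1 - weight_a) * b$intensity
  spectrum(id, grid, v, mz_window = range(grid))
}

# Deterministic largest-remainder allocation of n items to proportions.
allocate_counts <- function(n, proportions) {
  raw <- n * proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  as.integer(counts)
}

#' Generate annotated candidate matches against a reference library
#'
#' Labels are allocated deterministically at the configured proportions
#' (largest-remainder rule). A true-positive query is its paired reference
#' perturbed by noise, dropout and contaminants; a true-negative query is a
#' *different* library spectrum perturbed identically (so TN scores are
#' nontrivially high, as in real library search); an unknown query is a
#' blend of the paired reference (at `unknown_blend_weight`) and a decoy,
#' then perturbed.
#'
#' @param library List of [spectrum()] objects from [generate_library()].
#' @param config A [generator_config()].
#' @return A list of candidate matches, each a list with `match_id`,
#'   `query` and `reference` spectra, `annotation` (one of `true_positive`,
#'   `true_negative`, `unknown`), and `provenance` (which library spectra
#'   spawned the query).
#' @export
generate_matches <- function(library, config) {
  stopifnot(inherits(config, "generator_config"), length(library) >= 1L)
  counts <- allocate_counts(config$n_matches, config$label_proportions)
  labels <- rep(c("true_positive", "true_negative", "unknown"), counts)
  if (length(library) < 2L && any(labels != "true_positive")) {
    stop("need at least 2 library spectra to generate true negatives or unknowns",
         call. = FALSE)
  }
  with_seed(config$seed + 1L, {
    lapply(seq_along(labels), function(i) {
      lab <- labels[i]
      ref_idx <- sample.int(length(library), 1L)
      reference <- library[[ref_idx]]
      other_idx <- if (length(library) > 1L) {
        sample(setdiff(seq_along(library), ref_idx), 1L)
      } else ref_idx
      qid <- sprintf("QUERY_%05d", i)
      if (lab == "true_positive") {
        query <- perturb_spectrum(reference, qid, config)
        src <- reference$id
      } else if (lab == "true_negative") {
        query <- perturb_spectrum(library[[other_idx]], qid, config)
        src <- library[[other_idx]]$id
      } else {
        template <- blend_spectra(reference, library[[other_idx]],
                                  config$unknown_blend_weight, qid)
        query <- perturb_spectrum(template, qid, config)
        src <- paste0(reference$id, "+", library[[other_idx]]$id)
      }
      list(match_id = sprintf("MATCH_%05d", i),
           query = query,
           reference = reference,
           annotation = lab,
           provenance = list(query_source = src, reference = reference$id))
    })
  })
}

#' Score a set of candidate matches with all registered metrics
#'
#' Aligns each query/reference pair under the requested normalization and
#' computes all 66 metrics, returning the tidy score table that every
#' downstream stage consumes.
#'
#' @param matches List from [generate_matches()] (or any list of elements
#'   with `match_id`, `query`, `reference`, `annotation`).
#' @param mode Normalization mode, `"sum"` or `"max"`.
#' @param config A [metric_config()].
#' @return A tibble: `match_id`, `annotation`, then one column per metric.
#' @export
score_matches <- function(matches, mode = c("sum", "max"),
                          config = metric_config()) {
  mode <- match.arg(mode)
  scores <- t(vapply(matches, function(m) {
    compute_all_scores(align_spectra(m$query, m$reference, mode), config)
  }, numeric(nrow(list_metrics()))))
  out <- tibble::as_tibble(scores)
  out <- dplyr::bind_cols(
    tibble::tibble(match_id = vapply(matches, `[[`, character(1), "match_id"),
                   annotation = vapply(matches, `[[`, character(1), "annotation")),
    out)
  out
}

#' Write a candidate-match fixture to disk
#'
#' Emits `queries.msp` and `references.msp` (deduplicated by id),
#' `annotations.csv` (`match_id`, `query_id`, `reference_id`, `annotation`)
#' and `generator_config.json`; [read_spectra()] round-trips the spectra and
#' replaying the JSON config through [generate_library()] /
#' [generate_matches()] reproduces the identical dataset.
#'
#' @param matches List from [generate_matches()].
#' @param out_dir Output directory (created if needed).
#' @param config The [generator_config()] that produced `matches`.
#' @return `out_dir`, invisibly.
#' @export
write_fixture <- function(matches, out_dir, config = NULL) {
  stopifnot(length(matches) >= 1L)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  queries <- lapply(matches, `[[`, "query")
  refs <- lapply(matches, `[[`, "reference")
  refs <- refs[!duplicated(vapply(refs, `[[`, character(1), "id"))]
  write_spectra(queries, file.path(out_dir, "queries.msp"))
  write_spectra(refs, file.path(out_dir, "references.msp"))
  ann <- data.frame(
    match_id = vapply(matches, `[[`, character(1), "match_id"),
    query_id = vapply(matches, function(m) m$query$id, character(1)),
    reference_id = vapply(matches, function(m) m$reference$id, character(1)),
    annotation = vapply(matches, `[[`, character(1), "annotation"),
    stringsAsFactors = FALSE)
  utils::write.csv(ann, file.path(out_dir, "annotations.csv"), row.names = FALSE)
  if (!is.null(config)) {
    jsonlite::write_json(unclass(config), file.path(out_dir, "generator_config.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(out_dir)
}

#' Read a generator configuration back from a fixture
#'
#' @param path Path to a `generator_config.json` written by [write_fixture()].
#' @return A [generator_config()].
#' @export
read_generator_config <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(generator_config, j[setdiff(names(j), character())])
}
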