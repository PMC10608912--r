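# Fixture builders shared across test files. All randomness is seeded at
# the call site.

# A random aligned pair with partially overlapping support, exercising the
# zeros the full join introduces.
random_aligned_pair <- function(n_grid = NULL, mode = "sum") {
  if (is.null(n_grid)) n_grid <- sample(20:80, 1)
  n_a <- sample(ceiling(n_grid / 2):n_grid, 1)
  n_b <- sample(ceiling(n_grid / 2):n_grid, 1)
  grid <- sort(sample(50:550, n_grid))
  a <- spectrum("a", sample(grid, n_a), rexp(n_a))
  b <- spectrum("b", sample(grid, n_b), rexp(n_b))
  align_spectra(a, b, mode)
}

# Tiny scored dataset for evaluation/clustering tests.
tiny_score_table <- function(n_matches = 60, seed = 42, n_refs = 20,
                             mode = "sum", ...) {
  cfg <- generator_config(n_reference_spectra = n_refs,
                          n_matches = n_matches, seed = seed, ...)
  lib <- generate_library(cfg)
  score_matches(generate_matches(lib, cfg), mode)
}

# Mean score of every metric at each multiplicative noise level: each base
# spectrum is re-measured with log-normal intensity noise and scored against
# itself. Common random numbers across levels (one z draw per peak, scaled
# by the level) isolate the noise effect from resampling variation.
# Returns a 66 x length(noise_levels) matrix.
noise_degradation_means <- function(noise_levels, n_pairs, seed) {
  withr::with_seed(seed, {
    base <- lapply(seq_len(n_pairs), function(i) {
      n <- sample(15:30, 1)
      list(s = spectrum(paste0("b", i), sample(50:550, n), rexp(n)),
           z = rnorm(n))
    })
    sapply(noise_levels, function(sd) {
      sc <- sapply(base, function(b) {
        noisy <- spectrum("n", b$s$mz, b$s$intensity * exp(sd * b$z))
        compute_all_scores(align_spectra(noisy, b$s, "sum"))
      })
      rowMeans(sc, na.rm = TRUE)
    })
  })
}

# Feature table in which the cluster is an exact function of t-statistic
# and overlap score and every other predictor is uninformative noise.
forced_feature_table <- function(seed) {
  reg <- list_metrics()
  n <- nrow(reg)
  withr::with_seed(seed, {
    cluster <- sample(1:4, n, replace = TRUE)
    centers_t <- c(400, -400, -50, -150)
    centers_o <- c(0.02, 0.03, 0.14, 0.21)
    tibble::tibble(
      metric = reg$name,
      family = factor(sample(reg$family, n)),
      direction = factor(sample(c("distance", "similarity"), n, TRUE)),
      bound_direction = factor(sample(c("left", "both"), n, TRUE),
                               levels = c("left", "right", "both", "none")),
      score_min = rnorm(n),
      score_median = rnorm(n),
      score_max = rnorm(n, 5),
      t_statistic = centers_t[cluster] + rnorm(n, 0, 5),
      overlap_score = pmax(0, centers_o[cluster] + rnorm(n, 0, 0.003)),
      cluster = factor(cluster)
    )
  })
}
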