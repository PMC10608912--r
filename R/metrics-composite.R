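# Composite similarity scores: the Stein-Scott weighted-cosine/ratio
# composite and its transform-correlation relatives.

# Composite of (i) a squared weighted cosine on w = mz^mz_pow * abundance^int_pow
# and (ii) a peak-ratio term over consecutive m/z positions where both spectra
# have signal, combined with weights proportional to the query peak count and
# the common peak count. With no (or one) common position the ratio term is
# undefined and its weight shifts to the cosine term.
composite_similarity <- function(mz, P, Q, int_pow, mz_pow, cfg) {
  wp <- mz^mz_pow * P^int_pow
  wq <- mz^mz_pow * Q^int_pow
  cos2 <- sum(wp * wq)^2 / (sum(wp^2) * sum(wq^2))
  common <- which(P > 0 & Q > 0)
  n_q <- sum(P > 0)
  n_c <- length(common)
  if (n_c < 2L) return(cos2)
  i <- common[-1L]
  j <- common[-n_c]
  r <- (P[i] * Q[j]) / (P[j] * Q[i])
  r <- ifelse(r > 1, 1 / r, r)
  s_ratio <- mean(r)
  (n_q * cos2 + n_c * s_ratio) / (n_q + n_c)
}

#' Composite (Stein-Scott) spectral similarity
#'
#' The classic composite match factor for electron-ionization spectra: a
#' squared cosine between m/z- and intensity-weighted abundances, combined
#' with a relative-ratio term over the m/z positions shared by both spectra,
#' the two terms weighted by the query and common peak counts. The default
#' exponents are the classic optimum (intensity^0.6, m/z^3); the NIST search
#' convention (intensity^0.53, m/z^1.3) is available as the registry metric
#' `stein_scott_similarity_nist`.
#'
#' @inheritParams compute_score
#' @param variant `"classic"` or `"nist"`, selecting the weighting exponents
#'   from `config`.
#' @return Score in [0, 1]; 1 for identical spectra, 0 for disjoint support.
#' @export
stein_scott <- function(pair, variant = c("classic", "nist"),
                        config = metric_config()) {
  variant <- match.arg(variant)
  metric <- if (variant == "classic") "stein_scott_similarity" else "stein_scott_similarity_nist"
  compute_score(pair, metric, config)
}

# One full Haar pyramid: returns c(final approximation, detail coefficients
# from coarsest to finest). Input length must be a power of two.
haar_dwt <- function(x) {
  n <- length(x)
  details <- list()
  while (n > 1L) {
    even <- x[seq(1L, n, by = 2L)]
    odd  <- x[seq(2L, n, by = 2L)]
    x <- (even + odd) / sqrt(2)
    details[[length(details) + 1L]] <- (even - odd) / sqrt(2)
    n <- length(x)
  }
  c(x, unlist(rev(details)))
}

next_pow2 <- function(n) 2^ceiling(log2(max(n, 2L)))

transform_coefficients <- function(x, transform, cfg) {
  n <- next_pow2(length(x))
  x <- c(x, numeric(n - length(x)))
  keep <- max(1L, floor(n * cfg$transform_keep))
  if (transform == "dft") {
    z <- stats::fft(x)[seq_len(keep)]
    c(Re(z), Im(z))
  } else {
    haar_dwt(x)[seq_len(keep)]
  }
}

transform_composite <- function(mz, P, Q, transform, cfg) {
  wp <- mz^cfg$wc_mz_power * P^cfg$wc_int_power
  wq <- mz^cfg$wc_mz_power * Q^cfg$wc_int_power
  s_wc <- sum(wp * wq) / (sqrt(sum(wp^2)) * sqrt(sum(wq^2)))
  cp <- transform_coefficients(P, transform, cfg)
  cq <- transform_coefficients(Q, transform, cfg)
  if (stats::sd(cp) == 0 || stats::sd(cq) == 0) return(NaN)
  s_t <- stats::cor(cp, cq)
  n_q <- sum(P > 0)
  n_c <- sum(P > 0 & Q > 0)
  if (n_c == 0L) return(s_wc)
  (n_q * s_wc + n_c * s_t) / (n_q + n_c)
}

#' Transform-domain correlation similarity
#'
#' Correlation-type score between the low-order discrete Fourier (`"dft"`)
#' or Haar wavelet (`"dwt"`) transform coefficients of the two abundance
#' vectors, combined with an untransformed weighted-cosine term using the
#' same peak-count weighting as the composite similarity. Vectors are
#' zero-padded to the next power of two; the retained coefficient fraction,
#' the weighting exponents and the basis are set in [metric_config()].
#'
#' @inheritParams compute_score
#' @param transform `"dft"` or `"dwt"`.
#' @return Score in [-1, 1]; 1 for identical spectra. `NaN` when a
#'   coefficient vector has zero variance.
#' @export
transform_correlation <- function(pair, transform = c("dft", "dwt"),
                                  config = metric_config()) {
  transform <- match.arg(transform)
  metric <- if (transform == "dft") "dft_correlation" else "dwt_correlation"
  compute_score(pair, metric, config)
}
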