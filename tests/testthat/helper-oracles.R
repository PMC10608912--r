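# Independent naive implementations used as oracles. Everything here is
# coded elementwise with explicit loops, straight from the defining
# formulas and the documented zero policy (0/0 -> 0, additive eps on zero
# denominators/log arguments, final clamp at cap), sharing no code with the
# package implementations.

O_EPS <- 1e-13
O_CAP <- 1e12

o_term <- function(num, den) {
  if (num == 0 && den == 0) return(0)
  if (den == 0) den <- O_EPS
  num / den
}

o_log_ratio <- function(num, den) {
  if (num == 0) num <- O_EPS
  if (den == 0) den <- O_EPS
  log(num / den)
}

o_clamp <- function(v) {
  if (is.nan(v)) return(NaN)
  if (!is.finite(v) || abs(v) > O_CAP) return(sign(v) * O_CAP)
  v
}

o_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n; my <- sum(y) / n
  sxy <- 0; sxx <- 0; syy <- 0
  for (i in seq_len(n)) {
    sxy <- sxy + (x[i] - mx) * (y[i] - my)
    sxx <- sxx + (x[i] - mx)^2
    syy <- syy + (y[i] - my)^2
  }
  if (sxx == 0 || syy == 0) return(NaN)
  sxy / sqrt(sxx * syy)
}

o_midrank <- function(x) {
  n <- length(x)
  r <- numeric(n)
  for (i in seq_len(n)) {
    less <- 0; equal <- 0
    for (j in seq_len(n)) {
      if (x[j] < x[i]) less <- less + 1
      if (x[j] == x[i]) equal <- equal + 1
    }
    r[i] <- less + (equal + 1) / 2
  }
  r
}

o_kendall_b <- function(x, y) {
  n <- length(x)
  conc <- 0; disc <- 0; tx <- 0; ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      dx <- x[i] - x[j]; dy <- y[i] - y[j]
      s <- sign(dx) * sign(dy)
      if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
      else if (dx == 0) tx <- tx + 1
      else if (dy == 0) ty <- ty + 1
      else if (s > 0) conc <- conc + 1
      else disc <- disc + 1
    }
  }
  n0 <- n * (n - 1) / 2
  den <- sqrt((n0 - tx) * (n0 - ty))
  if (den == 0) return(NaN)
  (conc - disc) / den
}

# direct-summation DFT, O(n^2)
o_dft <- function(x) {
  n <- length(x)
  out <- complex(n)
  for (k in 0:(n - 1)) {
    acc <- 0 + 0i
    for (j in 0:(n - 1)) acc <- acc + x[j + 1] * exp(-2i * pi * j * k / n)
    out[k + 1] <- acc
  }
  out
}

# Haar coefficients via an explicit basis matrix: first the scaling row,
# then wavelet rows from coarsest to finest; each wavelet is +1/sqrt(L) on
# the first half of its support and -1/sqrt(L) on the second.
o_haar <- function(x) {
  n <- length(x)
  rows <- list(rep(1 / sqrt(n), n))
  L <- n
  while (L >= 2) {
    for (start in seq(1, n, by = L)) {
      w <- numeric(n)
      w[start:(start + L / 2 - 1)] <- 1 / sqrt(L)
      w[(start + L / 2):(start + L - 1)] <- -1 / sqrt(L)
      rows[[length(rows) + 1]] <- w
    }
    L <- L / 2
  }
  vapply(rows, function(w) sum(w * x), numeric(1))
}

o_pad2 <- function(x) {
  n <- 2^ceiling(log2(max(length(x), 2)))
  c(x, numeric(n - length(x)))
}

o_composite <- function(mz, P, Q, a, b) {
  wp <- numeric(length(P)); wq <- numeric(length(Q))
  for (i in seq_along(P)) {
    wp[i] <- mz[i]^b * P[i]^a
    wq[i] <- mz[i]^b * Q[i]^a
  }
  dot <- 0; np2 <- 0; nq2 <- 0
  for (i in seq_along(P)) {
    dot <- dot + wp[i] * wq[i]; np2 <- np2 + wp[i]^2; nq2 <- nq2 + wq[i]^2
  }
  cos2 <- dot^2 / (np2 * nq2)
  common <- integer(0)
  for (i in seq_along(P)) if (P[i] > 0 && Q[i] > 0) common <- c(common, i)
  nq <- sum(P > 0); nc <- length(common)
  if (nc < 2) return(cos2)
  rsum <- 0
  for (t in 2:nc) {
    i <- common[t]; j <- common[t - 1]
    r <- (P[i] * Q[j]) / (P[j] * Q[i])
    if (r > 1) r <- 1 / r
    rsum <- rsum + r
  }
  (nq * cos2 + nc * (rsum / (nc - 1))) / (nq + nc)
}

o_transform <- function(mz, P, Q, kind) {
  wp <- mz^1.3 * P^0.5; wq <- mz^1.3 * Q^0.5
  swc <- sum(wp * wq) / sqrt(sum(wp^2) * sum(wq^2))
  pp <- o_pad2(P); qq <- o_pad2(Q)
  keep <- length(pp) / 2
  if (kind == "dft") {
    zp <- o_dft(pp)[1:keep]; zq <- o_dft(qq)[1:keep]
    cp <- c(Re(zp), Im(zp)); cq <- c(Re(zq), Im(zq))
  } else {
    cp <- o_haar(pp)[1:keep]; cq <- o_haar(qq)[1:keep]
  }
  ct <- o_pearson(cp, cq)
  if (is.nan(ct)) return(NaN)
  nq <- sum(P > 0); nc <- sum(P > 0 & Q > 0)
  if (nc == 0) return(swc)
  (nq * swc + nc * ct) / (nq + nc)
}

# One naive implementation per registered metric; names match the registry.
oracle_metric <- function(name, mz, P, Q) {
  n <- length(P)
  acc <- 0
  v <- switch(name,
    manhattan_distance = sum(sapply(1:n, function(i) abs(P[i] - Q[i]))),
    euclidean_distance = sqrt(sum(sapply(1:n, function(i) (P[i] - Q[i])^2))),
    minkowski_3_distance = (sum(sapply(1:n, function(i) abs(P[i] - Q[i])^3)))^(1/3),
    chebyshev_distance = max(sapply(1:n, function(i) abs(P[i] - Q[i]))),
    sorensen_distance = sum(abs(P - Q)) / sum(P + Q),
    gower_distance = sum(abs(P - Q)) / n,
    soergel_distance = sum(abs(P - Q)) / sum(pmax(P, Q)),
    kulczynski_1_distance = o_term(sum(abs(P - Q)), sum(pmin(P, Q))),
    canberra_distance = { for (i in 1:n) acc <- acc + o_term(abs(P[i] - Q[i]), P[i] + Q[i]); acc },
    canberra_metric = { for (i in 1:n) acc <- acc + o_term(abs(P[i] - Q[i]), P[i] + Q[i]); acc / sum(P + Q > 0) },
    lorentzian_distance = sum(sapply(1:n, function(i) log(1 + abs(P[i] - Q[i])))),
    whittaker_index_of_association_distance =
      0.5 * sum(sapply(1:n, function(i) abs(P[i] / sum(P) - Q[i] / sum(Q)))),
    intersection_similarity = sum(pmin(P, Q)),
    intersection_distance = 0.5 * sum(abs(P - Q)),
    wave_hedges_distance = { for (i in 1:n) acc <- acc + o_term(abs(P[i] - Q[i]), max(P[i], Q[i])); acc },
    czekanowski_similarity = 2 * sum(pmin(P, Q)) / sum(P + Q),
    czekanowski_distance = sum(abs(P - Q)) / sum(P + Q),
    motyka_similarity = sum(pmin(P, Q)) / sum(P + Q),
    motyka_distance = sum(pmax(P, Q)) / sum(P + Q),
    kulczynski_2_similarity = o_term(sum(pmin(P, Q)), sum(abs(P - Q))),
    ruzicka_similarity = sum(pmin(P, Q)) / sum(pmax(P, Q)),
    tanimoto_distance = sum(pmax(P, Q) - pmin(P, Q)) / sum(pmax(P, Q)),
    inner_product_similarity = sum(P * Q),
    harmonic_mean_similarity = { for (i in 1:n) acc <- acc + o_term(P[i] * Q[i], P[i] + Q[i]); 2 * acc },
    cosine_correlation = sum(P * Q) / sqrt(sum(P^2) * sum(Q^2)),
    kumar_hassebrook_similarity = sum(P * Q) / (sum(P^2) + sum(Q^2) - sum(P * Q)),
    jaccard_distance = 1 - sum(P * Q) / (sum(P^2) + sum(Q^2) - sum(P * Q)),
    dice_similarity = 2 * sum(P * Q) / (sum(P^2) + sum(Q^2)),
    dice_distance = 1 - 2 * sum(P * Q) / (sum(P^2) + sum(Q^2)),
    weighted_cosine_correlation = {
      wp <- mz^1.3 * P^0.5; wq <- mz^1.3 * Q^0.5
      sum(wp * wq) / sqrt(sum(wp^2) * sum(wq^2))
    },
    stein_scott_similarity = o_composite(mz, P, Q, 0.6, 3),
    stein_scott_similarity_nist = o_composite(mz, P, Q, 0.53, 1.3),
    dft_correlation = o_transform(mz, P, Q, "dft"),
    dwt_correlation = o_transform(mz, P, Q, "dwt"),
    fidelity_similarity = sum(sqrt(P * Q)),
    bhattacharyya_distance = { f <- sum(sqrt(P * Q)); if (f == 0) f <- O_EPS; -log(f) },
    hellinger_distance = sqrt(2 * sum((sqrt(P) - sqrt(Q))^2)),
    matusita_distance = sqrt(sum((sqrt(P) - sqrt(Q))^2)),
    squared_chord_distance = sum((sqrt(P) - sqrt(Q))^2),
    squared_chord_similarity = 2 * sum(sqrt(P * Q)) - 1,
    squared_euclidean_distance = sum((P - Q)^2),
    pearson_chi_squared_distance = { for (i in 1:n) acc <- acc + o_term((P[i] - Q[i])^2, Q[i]); acc },
    neyman_chi_squared_distance = { for (i in 1:n) acc <- acc + o_term((P[i] - Q[i])^2, P[i]); acc },
    squared_chi_squared_distance = { for (i in 1:n) acc <- acc + o_term((P[i] - Q[i])^2, P[i] + Q[i]); acc },
    probabilistic_symmetric_chi_squared_distance =
      { for (i in 1:n) acc <- acc + o_term((P[i] - Q[i])^2, P[i] + Q[i]); 2 * acc },
    divergence_distance = { for (i in 1:n) acc <- acc + o_term((P[i] - Q[i])^2, (P[i] + Q[i])^2); 2 * acc },
    clark_distance = { for (i in 1:n) acc <- acc + o_term(abs(P[i] - Q[i]), P[i] + Q[i])^2; sqrt(acc) },
    additive_symmetric_chi_squared_distance =
      { for (i in 1:n) acc <- acc + o_term((P[i] - Q[i])^2 * (P[i] + Q[i]), P[i] * Q[i]); acc },
    kullback_leibler_divergence =
      { for (i in 1:n) if (P[i] > 0) acc <- acc + P[i] * o_log_ratio(P[i], Q[i]); acc },
    jeffreys_divergence =
      { for (i in 1:n) if (P[i] != Q[i]) acc <- acc + (P[i] - Q[i]) * o_log_ratio(P[i], Q[i]); acc },
    k_divergence =
      { for (i in 1:n) if (P[i] > 0) acc <- acc + P[i] * o_log_ratio(2 * P[i], P[i] + Q[i]); acc },
    topsoe_distance = {
      for (i in 1:n) {
        if (P[i] > 0) acc <- acc + P[i] * o_log_ratio(2 * P[i], P[i] + Q[i])
        if (Q[i] > 0) acc <- acc + Q[i] * o_log_ratio(2 * Q[i], P[i] + Q[i])
      }
      acc
    },
    jensen_shannon_divergence = {
      for (i in 1:n) {
        if (P[i] > 0) acc <- acc + P[i] * o_log_ratio(2 * P[i], P[i] + Q[i])
        if (Q[i] > 0) acc <- acc + Q[i] * o_log_ratio(2 * Q[i], P[i] + Q[i])
      }
      acc / 2
    },
    jensen_difference_distance = {
      for (i in 1:n) {
        plogp <- if (P[i] > 0) P[i] * log(P[i]) else 0
        qlogq <- if (Q[i] > 0) Q[i] * log(Q[i]) else 0
        s <- (P[i] + Q[i]) / 2
        slogs <- if (s > 0) s * log(s) else 0
        acc <- acc + (plogp + qlogq) / 2 - slogs
      }
      acc
    },
    kumar_johnson_divergence =
      { for (i in 1:n) acc <- acc + o_term((P[i]^2 - Q[i]^2)^2, 2 * (P[i] * Q[i])^1.5); acc },
    vicis_wave_hedges_distance =
      { for (i in 1:n) acc <- acc + o_term(abs(P[i] - Q[i]), min(P[i], Q[i])); acc },
    vicis_symmetric_chi_squared_1_distance =
      { for (i in 1:n) acc <- acc + o_term((P[i] - Q[i])^2, min(P[i], Q[i])^2); acc },
    vicis_symmetric_chi_squared_2_distance =
      { for (i in 1:n) acc <- acc + o_term((P[i] - Q[i])^2, min(P[i], Q[i])); acc },
    vicis_symmetric_chi_squared_3_distance =
      { for (i in 1:n) acc <- acc + o_term((P[i] - Q[i])^2, max(P[i], Q[i])); acc },
    max_symmetric_chi_squared_distance = {
      a <- 0; b <- 0
      for (i in 1:n) {
        a <- a + o_term((P[i] - Q[i])^2, P[i]); b <- b + o_term((P[i] - Q[i])^2, Q[i])
      }
      max(a, b)
    },
    min_symmetric_chi_squared_distance = {
      a <- 0; b <- 0
      for (i in 1:n) {
        a <- a + o_term((P[i] - Q[i])^2, P[i]); b <- b + o_term((P[i] - Q[i])^2, Q[i])
      }
      min(a, b)
    },
    average_l1_linf_distance = (sum(abs(P - Q)) + max(abs(P - Q))) / 2,
    taneja_divergence = {
      for (i in 1:n) {
        s <- P[i] + Q[i]
        if (s > 0) acc <- acc + (s / 2) * o_log_ratio(s, 2 * sqrt(P[i] * Q[i]))
      }
      acc
    },
    pearson_correlation = o_pearson(P, Q),
    spearman_correlation = o_pearson(o_midrank(P), o_midrank(Q)),
    kendall_tau_correlation = o_kendall_b(P, Q),
    stop("oracle missing for metric: ", name)
  )
  o_clamp(v)
}

# Welch statistic via the reference implementation in stats
o_welch <- function(x, y) unname(stats::t.test(x, y, var.equal = FALSE)$statistic)

# sort-and-interpolate quantile at position (n-1)*q, then count membership
o_quantile <- function(v, q) {
  v <- sort(v)
  h <- (length(v) - 1) * q
  lo <- floor(h)
  v[lo + 1] + (h - lo) * (v[min(lo + 2, length(v))] - v[lo + 1])
}

o_overlap <- function(tp, tn, unk) {
  in_iqr <- function(x, g) {
    if (length(g) == 0) return(rep(FALSE, length(x)))
    x >= o_quantile(g, 0.25) & x <= o_quantile(g, 0.75)
  }
  hits <- 0
  for (v in tp) if (in_iqr(v, tn) || in_iqr(v, unk)) hits <- hits + 1
  hits / length(tp)
}

# naive O(n^3) complete-linkage agglomeration on dissimilarity d = 1 - r,
# merge ties broken by lowest pair index; returns k-group memberships
o_complete_linkage <- function(corr, k) {
  n <- nrow(corr)
  d <- 1 - corr
  groups <- as.list(seq_len(n))
  while (length(groups) > k) {
    best <- c(NA, NA); best_d <- Inf
    for (a in 1:(length(groups) - 1)) {
      for (b in (a + 1):length(groups)) {
        dd <- max(d[groups[[a]], groups[[b]]])
        if (dd < best_d) { best_d <- dd; best <- c(a, b) }
      }
    }
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  out <- integer(n)
  for (g in seq_along(groups)) out[groups[[g]]] <- g
  out
}

# do two cluster labelings define the same partition?
same_partition <- function(a, b) {
  identical(match(a, unique(a)), match(b, unique(b)))
}
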