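test_that("registry holds 66 uniquely named metrics across the ten families", {
  reg <- list_metrics()
  expect_equal(nrow(reg), 66)
  expect_equal(anyDuplicated(reg$name), 0)
  fams <- c("Chi Squared", "Correlative", "Fidelity", "Inner Product",
            "Intersection", "L1", "Lp", "Shannon's Entropy",
            "Vicis Wave Hedges", "Combined")
  expect_setequal(unique(reg$family), fams)
  expect_true(all(reg$direction %in% c("similarity", "distance")))
  expect_true(all(reg$lower < reg$upper))
  # every registered name resolves through compute_score
  pr <- withr::with_seed(1, random_aligned_pair())
  for (m in reg$name) expect_true(is.numeric(compute_score(pr, m)), info = m)
  expect_error(compute_score(pr, "no_such_metric"), "unknown metric")
})

test_that("hand-computed scores match: cosine 8/9, Manhattan 0.6", {
  # raw vectors (1,2,2) vs (2,1,2): dot = 8, norms = 3, cosine = 8/9
  q <- spectrum("q", c(70, 85, 99), c(1, 2, 2))
  r <- spectrum("r", c(70, 85, 99), c(2, 1, 2))
  pr <- align_spectra(q, r, "sum")  # common scale drops out of the cosine
  expect_equal(compute_score(pr, "cosine_correlation"), 8 / 9, tolerance = 1e-12)

  # sum-scaled (0.2, 0.8) vs (0.5, 0.5): sum |d| = 0.6
  q2 <- spectrum("q", c(70, 85), c(0.2, 0.8))
  r2 <- spectrum("r", c(70, 85), c(0.5, 0.5))
  expect_equal(compute_score(align_spectra(q2, r2, "sum"), "manhattan_distance"),
               0.6, tolerance = 1e-12)
})

test_that("identical spectra yield the forced extremal score for every metric", {
  reg <- list_metrics()
  withr::with_seed(3, {
    for (rep in 1:3) {
      n <- sample(10:30, 1)
      s <- spectrum("s", sample(50:550, n), rexp(n))
      pr <- align_spectra(s, s, "sum")
      for (i in seq_len(nrow(reg))) {
        if (is.na(reg$identity[i])) next
        expect_equal(compute_score(pr, reg$name[i]), reg$identity[i],
                     tolerance = 1e-9, info = reg$name[i])
      }
    }
  })
})

test_that("sampled scores respect the declared theoretical bounds under sum scaling", {
  reg <- list_metrics()
  withr::with_seed(8, {
    for (rep in 1:20) {
      pr <- random_aligned_pair()
      sc <- compute_all_scores(pr)
      for (i in seq_len(nrow(reg))) {
        v <- sc[[reg$name[i]]]
        if (is.nan(v)) next
        expect_gte(v, reg$lower[i] - 1e-9)
        if (is.finite(reg$upper[i])) expect_lte(v, reg$upper[i] + 1e-9)
      }
    }
  })
})

test_that("metrics documented as symmetric are symmetric; directed divergences are exempt", {
  reg <- list_metrics()
  swap_pair <- function(pr) {
    out <- pr
    out$P <- pr$Q; out$Q <- pr$P
    out
  }
  asym_seen <- setNames(rep(FALSE, sum(!reg$symmetric)), reg$name[!reg$symmetric])
  withr::with_seed(21, {
    for (rep in 1:10) {
      pr <- random_aligned_pair()
      rev <- swap_pair(pr)
      for (i in seq_len(nrow(reg))) {
        a <- compute_score(pr, reg$name[i])
        b <- compute_score(rev, reg$name[i])
        if (reg$symmetric[i]) {
          expect_equal(a, b, tolerance = 1e-9, info = reg$name[i])
        } else if (!isTRUE(all.equal(a, b, tolerance = 1e-9))) {
          asym_seen[reg$name[i]] <- TRUE
        }
      }
    }
  })
  # the directed forms really are directed on at least one sampled pair
  expect_true(all(asym_seen))
})

test_that("correlative metrics reproduce the textbook values on fixed vectors", {
  mk <- function(int_q, int_r) {
    q <- spectrum("q", c(70, 80, 90, 100), int_q)
    r <- spectrum("r", c(70, 80, 90, 100), int_r)
    align_spectra(q, r, "sum")
  }
  up <- mk(c(1, 2, 3, 4), c(1, 2, 3, 4))
  dn <- mk(c(1, 2, 3, 4), c(4, 3, 2, 1))
  for (m in c("pearson_correlation", "spearman_correlation", "kendall_tau_correlation")) {
    expect_equal(compute_score(up, m), 1, info = m)
    expect_equal(compute_score(dn, m), -1, info = m)
  }
})

test_that("compute_all_scores equals the per-metric loop, in registry order", {
  pr <- withr::with_seed(14, random_aligned_pair())
  all_sc <- compute_all_scores(pr)
  expect_length(all_sc, 66)
  expect_identical(names(all_sc), list_metrics()$name)
  loop <- vapply(list_metrics()$name, function(m) compute_score(pr, m), numeric(1))
  expect_identical(unname(all_sc), unname(loop))
})

test_that("every metric agrees with its independent naive oracle on random pairs", {
  reg <- list_metrics()
  withr::with_seed(101, {
    for (rep in 1:25) {
      pr <- random_aligned_pair(mode = if (rep %% 2) "sum" else "max")
      sc <- compute_all_scores(pr)
      for (m in reg$name) {
        o <- oracle_metric(m, pr$mz, pr$P, pr$Q)
        if (is.nan(o)) {
          expect_true(is.nan(sc[[m]]), info = m)
        } else {
          expect_equal(sc[[m]], o, tolerance = 1e-10, info = m)
        }
      }
    }
  })
})

test_that("intersection-family scores hit the no-overlap bound on disjoint support", {
  q <- spectrum("q", c(70, 85), c(1, 2))
  r <- spectrum("r", c(99, 120), c(2, 1))
  pr <- align_spectra(q, r, "sum")
  expect_equal(compute_score(pr, "intersection_similarity"), 0)
  expect_equal(compute_score(pr, "ruzicka_similarity"), 0)
  expect_equal(compute_score(pr, "motyka_similarity"), 0)
  expect_equal(compute_score(pr, "cosine_correlation"), 0)
})

test_that("composite similarity: identity, disjoint support, and the step-by-step oracle", {
  s <- spectrum("s", c(70, 81, 95, 110, 152), c(10, 40, 100, 25, 5))
  idp <- align_spectra(s, s, "sum")
  expect_equal(stein_scott(idp), 1, tolerance = 1e-12)
  expect_equal(stein_scott(idp, "nist"), 1, tolerance = 1e-12)

  r <- spectrum("r", c(60, 75, 90), c(1, 1, 1))
  dj <- align_spectra(s, r, "sum")
  expect_equal(stein_scott(dj), 0, tolerance = 1e-12)

  # fixed 5-peak pair: frozen value from the independent term-by-term oracle
  q2 <- spectrum("q", c(70, 81, 95, 110, 152), c(12, 35, 90, 30, 8))
  r2 <- spectrum("r", c(70, 81, 95, 130), c(10, 40, 100, 15))
  pr <- align_spectra(q2, r2, "sum")
  expect_equal(stein_scott(pr),
               o_composite(pr$mz, pr$P, pr$Q, 0.6, 3), tolerance = 1e-12)
  expect_equal(stein_scott(pr, "nist"),
               o_composite(pr$mz, pr$P, pr$Q, 0.53, 1.3), tolerance = 1e-12)
})

test_that("transform correlations: identity is 1 and scaling the reference is irrelevant", {
  s <- spectrum("s", c(70, 81, 95, 110, 152), c(10, 40, 100, 25, 5))
  idp <- align_spectra(s, s, "sum")
  expect_equal(transform_correlation(idp, "dft"), 1, tolerance = 1e-9)
  expect_equal(transform_correlation(idp, "dwt"), 1, tolerance = 1e-9)

  # positive rescaling of intensities vanishes under sum normalization,
  # leaving the whole score unchanged
  q <- spectrum("q", c(70, 85, 99), c(1, 2, 3))
  r1 <- spectrum("r", c(70, 85, 120), c(2, 1, 1))
  r2 <- spectrum("r", c(70, 85, 120), 7.3 * c(2, 1, 1))
  expect_equal(transform_correlation(align_spectra(q, r1, "sum"), "dft"),
               transform_correlation(align_spectra(q, r2, "sum"), "dft"),
               tolerance = 1e-12)

  # disjoint support: frozen against the direct-summation transform oracle
  a <- spectrum("a", c(70, 85), c(1, 1))
  b <- spectrum("b", c(99, 120), c(1, 1))
  dj <- align_spectra(a, b, "sum")
  expect_equal(transform_correlation(dj, "dft"),
               o_transform(dj$mz, dj$P, dj$Q, "dft"), tolerance = 1e-12)
  expect_equal(transform_correlation(dj, "dwt"),
               o_transform(dj$mz, dj$P, dj$Q, "dwt"), tolerance = 1e-12)
})
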