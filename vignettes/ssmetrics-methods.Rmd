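---
title: "Methods: spectral similarity metrics, separation statistics, and metric clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral similarity metrics, separation statistics, and metric clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`ssmetrics` evaluates how well spectral similarity (SS) scores separate
correct from incorrect GC-MS library matches. This vignette records the
model behind each stage, the tunable parameters and why their defaults are
what they are, the numerical policies, and the limits of what the synthetic
data can show.

## Spectra, abundances and the full join

A spectrum is a centroided set of (m/z, intensity) peaks from a
unit-resolution single-quadrupole instrument. The package therefore works
on nominal masses: m/z is rounded to the nearest integer at construction
and duplicates merged by summing. Peaks outside a configurable acquisition
window (default 50–550 Da, the usual range for silylated metabolite
fragments) are dropped with a message.

Before any comparison, intensities are scaled **per spectrum** to
*abundances*: either by the spectrum total (`sum`, giving a probability
vector) or by its maximum (`max`). A query/reference pair is then *fully
joined* by m/z: the grid is the union of both spectra's masses and a
spectrum missing a mass carries abundance 0 there.

Normalization deliberately precedes the join. Scaling is a per-spectrum
operation, and applying it after the join would let the zeros introduced
by the *other* spectrum's peaks change nothing for `sum` but feel
arbitrary for `max`; more importantly, pre-join scaling guarantees that a
query's abundance vector is identical whatever reference it is compared
against — total abundance conservation, which the tests assert.

## The 66-metric registry

The registry groups its 66 scores into the ten families conventional for
distance measures between probability vectors (the Cha taxonomy): Chi
Squared, Correlative, Fidelity, Inner Product, Intersection, L1, Lp,
Shannon's Entropy, Vicis Wave Hedges, and Combined — the last holding
exactly the two hybrids that fit nowhere else, the average (L1, L∞)
distance and the Taneja divergence. Several quantities appear in both a
similarity and a distance form (Dice, Czekanowski, Motyka, intersection);
that is deliberate, since part of the point of the downstream clustering
is that direction, not mathematical family, dominates empirical behaviour.
Direction is registry metadata only — no score is negated onto a common
orientation, so anti-correlated similarity/distance blocks can emerge in
the correlation structure.

Each entry records theoretical bounds (declared under the `sum`
convention, where vectors are probability-like), a derived bound direction
(left/right/both/none) used later as a random-forest predictor, whether
the metric is symmetric in its arguments, and the score forced on
identical spectra. Four composites are registered asymmetric on purpose:
the Stein-Scott composite (classic and NIST weighting) and the DFT/DWT
correlations weight their terms by the *query* peak count, following the
original composite match-factor definition.

Three weighted-score conventions are config-exposed in `metric_config()`:

* `stein_scott_similarity`: weights `w_i = m_i^3 · a_i^0.6`, the classic
  exponent pair for EI spectra; the cosine term is squared (a match-factor
  convention) and the ratio term averages consecutive common-peak
  abundance ratios, flipped to lie in (0, 1].
* `stein_scott_similarity_nist`: identical structure with `m^1.3 ·
  a^0.53`, the NIST search weighting.
* `weighted_cosine_correlation` (also the cosine term of the transform
  composites): plain cosine on `m^1.3 · a^0.5`.

The transform correlations zero-pad the abundance vectors to the next
power of two, transform (DFT via the FFT; DWT with the Haar pyramid — the
only basis implemented, chosen because it is parameter-free and exact on
dyadic lengths), keep the low-order half of the coefficients (real and
imaginary parts for the DFT), and Pearson-correlate them; the result is
blended with the weighted cosine using the composite's peak-count weights.
Padding, retained fraction and basis are exposed because no single
convention dominates the literature.

### Zero handling

The full join makes zeros ubiquitous, so every metric follows one written
policy: `0/0` and `0·log 0` terms are 0; a denominator or log argument
that must be strictly positive but is exactly 0 receives an additive
`eps = 1e-13`; any score whose magnitude still overflows (left-bounded
distances on near-disjoint support, e.g. the Vicis Wave Hedges family) is
clamped to `cap = 1e12`. Both constants sit in `metric_config()`. The
independent oracle implementations in the test suite encode the same
policy, because the policy is part of each metric's definition here.

## Separation statistics

For each metric the package computes the **signed Welch t-statistic**
between true-positive and true-negative scores,
`(x̄_TP − x̄_TN)/√(s²_TP/n_TP + s²_TN/n_TN)`. The unequal-variance form is
the safe default since TP and TN score distributions have very different
spreads; the statistic itself (not a p-value) is the evaluation quantity,
and its sign encodes direction: positive for similarity-type metrics,
negative for distance-type ones, when the metric separates correctly.

The **overlap score** is the fraction of true-positive scores inside the
inner-quartile range (closed interval, 25th–75th percentile) of the
true-negative distribution *or* of the unknown distribution. Quartiles use
linear interpolation between order statistics at position `(n−1)·q`
(R type 7) — stated explicitly because quantile conventions move the third
decimal at small n. The union of the two IQRs is the default reading of
"overlap with the true-negative and unknown distributions"; a pooled
alternative (`method = "pooled"`) is available. Unknowns enter only the
overlap score, never the t-statistic, whose contrast is TP vs TN as
defined.

Degenerate inputs are resolved explicitly: both groups constant with equal
means gives t = 0; constant with different means gives a signed infinity
(capped if it ever reaches the random-forest feature table); fewer than
two finite scores per group is an error; NaN scores are dropped with a
logged count.

## Metric clustering

Scores for all candidate matches are correlated metric-against-metric
(Pearson, pairwise-complete observations; zero-variance columns dropped
with a warning). Agglomeration is complete-linkage on `d = 1 − r`, so
"highly correlated" directly means "close"; clustering on Euclidean
distances between correlation rows is available behind a flag, since
heatmap tools often default to it, but `1 − r` is the default because the
intent is to group metrics that rank matches the same way. The dendrogram
is cut at `k` (default 4; a parameter, not an automatic selection — the
number of visually distinct blocks is a judgement the user should make on
the heatmap). Cluster ids are relabelled contiguously in input order so a
fixed input yields a fixed labelling; assignments are invariant to metric
permutations up to relabelling, which the tests check against a naive
all-pairs agglomeration oracle.

## Random-forest characterization

A classifier predicting each metric's empirical cluster from its
attributes (family, direction, bound direction, pooled min/median/max
score, t-statistic, overlap score) quantifies *what defines the clusters*.
Implementation choices:

* 75/25 train/test split with half-up rounding, so 66 metrics give
  exactly 50/16; class balance between partitions is reported.
* "Cross validation with 10% holdout, five times" is read as five
  independent Monte-Carlo 90/10 splits (`scheme = "mc"`), switchable to
  5-fold CV; with ~50 rows, MC splits are the less brittle reading.
* The tuning grid spans trees {500, 1000, 1395, 2000}, variables per
  split {2, 3, 4} and minimum node size {1, 5}; grid bounds are choices,
  kept wide enough that the selected point is interior in practice. Ties
  resolve to the lowest grid index.
* Importances are Gini (impurity) importances from `ranger`, scaled so
  the maximum is exactly 100; a factor predictor carries one importance
  (no per-level indicator splitting), giving one bar per named attribute.
* Every seed (split, CV, forest) is an explicit argument and is logged in
  the pipeline manifest; the characterization is bit-reproducible given
  the seed triple.

## The synthetic candidate-match generator

The generator produces data with the statistical structure library search
creates, not a physical simulation of chromatography:

* **Library**: integer m/z sampled without replacement on 50–550 Da;
  20–40 peaks per compound (typical for silylated small-molecule EI
  spectra at unit resolution); exponential intensities (a few dominant
  fragments, many minor ones), scaled to max 100.
* **True positives**: the paired reference corrupted by log-normal
  multiplicative intensity noise (log-scale SD 0.25 ≈ 25% replicate
  variability), 5% per-peak dropout (minor peaks vanish near the
  detection limit), and Poisson(1) contaminant peaks at one tenth of the
  base intensity scale (background/co-elution artefacts).
* **True negatives**: a *different* library spectrum corrupted
  identically — reusing real library spectra keeps TN scores nontrivially
  high, as in real search, instead of comparing against noise.
* **Unknowns**: an abundance-space blend of the paired reference (weight
  0.3) with a decoy, then corrupted. Modelling unknowns as
  partial-evidence mixtures reflects what the annotation means in
  practice — matches an expert cannot confirm but will not rule out; the
  blend weight is the knob that moves unknowns between TN-like and
  TP-like regimes, and at weight ≤ 0.3 the unknown cosine median sits
  between the TN and TP medians (asserted in tests).
* **Labels**: allocated deterministically by largest remainder at
  proportions 40/40/20 TP/TN/unknown — balanced enough for stable
  t-statistics while keeping all three classes populated.

The shipped study scale is 200 reference compounds and 5000 candidate
matches: large enough that metric-metric correlations and t-statistics
stabilize, small enough for minutes-scale runs; the monotone-degradation
experiment uses 200 self-match pairs per noise level and the
oracle-equivalence checks 100 random aligned pairs. Everything is a pure
function of the configuration seed, down to byte-identical fixture files.

What the generator does **not** emulate: retention-time structure,
deconvolution artefacts, correlated (isotope/adduct) peak groups,
mass-dependent intensity trends, or class imbalance as extreme as real
annotated corpora (where unknowns dominate). Consequently, passing the
pipeline's qualitative checks here says the *machinery* behaves — e.g.
that direction splits the metrics at k = 2 with anti-correlated blocks —
not that any particular metric will win on real data, and absolute score
distributions or cluster counts (k = 4 on real corpora) are not expected
to transfer.

## Noise-degradation experiment

The degradation invariant — more multiplicative noise should lower every
similarity-direction mean score and raise every distance-direction one —
is tested at five log-scale SD levels (0.1, 0.25, 0.5, 1.0, 2.0) with a
one-sided Spearman trend test at α = 0.01 per metric, using **common
random numbers**: one standard-normal draw per peak, scaled by the level,
so the five means per metric differ only through the noise level. CRN
matters because the raw inner product responds only at second order near
zero noise (its leading per-pair term averages ≈ −2/n² for n peaks);
without pairing, resampling error exceeds the true effect at the small-SD
end and the trend test fails spuriously. Even with CRN the inner product's
expected change over the smallest gap is of order 1e-4, so for unlucky
base-spectrum samples it can dip below Monte-Carlo resolution — the one
known fragility of this invariant; all other 65 metrics respond strongly.

## Known limitations

* The nominal-mass join (round to integer) is right for single-quadrupole
  data but wrong for high-resolution instruments; no tolerance-based
  matching is implemented.
* Clamped scores (cap 1e12) make the affected Vicis Wave Hedges / χ²
  metrics behave as censored variables in the correlation matrix; that is
  faithful to how they explode on disjoint support but means their
  correlations partly reflect the censoring.
* The Jensen difference and Jensen–Shannon forms are algebraically
  identical (both are kept, as the taxonomy lists both), so one pair of
  correlation-matrix entries is exactly 1 by construction.
* No FDR machinery: the threshold sweep reports raw TP/TN passing
  fractions only.
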