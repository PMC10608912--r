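Package: ssmetrics
Title: Evaluating Spectral Similarity Metrics for GC-MS Compound Identification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes 66 spectral similarity and distance metrics from ten
    mathematical families between query and reference GC-MS electron-ionization
    mass spectra, evaluates how well each metric separates true-positive from
    true-negative and unknown candidate matches (Welch t-statistic and
    inner-quartile overlap score), groups metrics by complete-linkage
    agglomerative clustering of their pairwise Pearson correlations, and
    characterizes cluster membership with a tuned random-forest classifier.
    Includes a seeded generator of annotated synthetic candidate-match datasets
    (reference library, noisy true-positive queries, mismatched true negatives,
    blended unknowns) so the full pipeline runs without external data, plus
    MSP and long-format CSV spectrum I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    jsonlite,
    ranger,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
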