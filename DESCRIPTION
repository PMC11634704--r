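Package: markerdrift
Title: Sparse One-vs-All Wilcoxon Marker Detection and Immune Identity-Drift Analytics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Single-pass, tie-corrected one-vs-all-others Wilcoxon rank-sum
    marker detection for sparse single-cell count matrices, together with
    analytics for age-related loss of cell-type identity: age-decile grouping
    with balanced downsampling, marker-count trajectories, composition by
    decile, PCA distance-to-centroid dispersion and convergence statistics,
    and gene-signature aging scores. Includes a synthetic single-cell atlas
    generator with planted markers and age-dependent dispersion or
    convergence regimes, so every analysis is testable against known ground
    truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    jsonlite,
    methods,
    optparse,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
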