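Package: eispot
Title: Excitatory/Inhibitory Balance Scoring for Spatial Transcriptomics Spots
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Visium-style spatial transcriptomics of the
    mouse hippocampus: spot/gene quality control and log-normalization,
    marker-based assignment of CA1/CA3/DG subregions, per-spot gene-set
    variation scores for glutamatergic and GABAergic synapse signatures via a
    rank-based Kolmogorov-Smirnov random walk, median-split classification of
    spots into excitatory/inhibitory/mixed categories with group proportion
    statistics, a rank-sum differential-expression screen with
    Benjamini-Hochberg correction, and spatial-similarity prioritization of
    candidate genes. Includes a negative-binomial Visium-like simulator with
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
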