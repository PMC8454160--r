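Package: molUQ
Title: Hybrid Uncertainty Quantification for Molecular Property Regression
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-agnostic uncertainty quantification for QSAR-style
    regression. Provides four individual uncertainty estimators
    (mean-variance estimation, deep-ensemble variance, fingerprint
    nearest-neighbor distance, latent-space nearest-neighbor distance),
    the additive Bayesian total-uncertainty baseline, two consensus
    strategies (normalized weighted averaging and post-hoc negative
    log-likelihood calibration on a validation set), ranking and
    calibration evaluation metrics (Spearman correlation, confidence
    curves, ECE, ENCE, reliability diagrams), domain-shift
    cross-validation splitters built on single-linkage clustering of
    fingerprint distances, and an inductive conformal prediction
    comparator with the ensemble-standard-deviation nonconformity
    function. A synthetic-data generator with known heteroskedastic
    noise makes every stage testable without chemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    ChemmineOB,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
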