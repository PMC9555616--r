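Package: sacnirs
Title: Systemic Activity Correction Methods for fNIRS Time Series
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for evaluating systemic-activity correction (SAC) in
    functional near-infrared spectroscopy (fNIRS). Provides a synthetic
    cohort generator for dual-wavelength intensity recordings with
    spatially coherent physiological interference (Mayer-wave,
    respiratory, cardiac bands), a preprocessing chain (optical density
    conversion, channel quality pruning via scalp coupling index and peak
    spectral power, temporal derivative distribution repair, the modified
    Beer-Lambert law with age-dependent pathlength factors, zero-phase
    band-pass filtering, canonical-HRF semisimulation), five correction
    methods with and without short-distance channels (common average
    reference, Gaussian-kernel SVD global component removal, short
    separation regression, and two short-distance-channel GLM variants
    solved by AR-prewhitened robust least squares), single-trial signal
    quality metrics (scaled RMSE, Spearman HRF correlation, contrast-to-
    noise ratio), spatial specificity summaries (channel-SDC correlation
    matrices, group beta maps), and a Jeffreys-Zellner-Siow Bayes-factor
    evidence layer for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'bayes.R'
    'constants.R'
    'preprocess.R'
    'probe.R'
    'correct.R'
    'hrf.R'
    'glm.R'
    'evaluate.R'
    'simulate.R'
    'io.R'
    'metrics.R'
    'quality.R'
    'spatial.R'
    'report.R'
    'sacnirs-package.R'
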