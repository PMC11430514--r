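Package: qeegperm
Title: Quantitative EEG and ERP Group Comparison with Wilcoxon Z-Sum
    Cluster-Based Permutation Tests
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulation and analysis pipeline for quantitative EEG (QEEG)
    and event-related potential (ERP) studies of small patient cohorts
    against normative control groups. Provides a seeded multichannel EEG
    generator for a cued GO/NOGO paradigm (1/f background, narrow-band
    alpha sources with scalp topographies, stimulus-locked ERP components,
    ocular and gross artifacts, behavioral scores with controlled
    correlation structure), a preprocessing chain (zero-phase Butterworth
    filtering, notch, weighted-average re-referencing, seeded FastICA
    ocular correction, three-rule amplitude artifact rejection), Welch
    spectral analysis with relative amplitudes, per-condition ERP
    averaging and component quantification, and a nonparametric
    cluster-based permutation test whose pointwise statistic is the
    normal-approximation Wilcoxon z (signed-rank or rank-sum) and whose
    cluster mass is the summed z-score, with a max-statistic permutation
    null. Includes Pearson correlation of ERP component amplitudes with
    behavioral scores and a reproducible markdown report builder.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    graphics,
    utils,
    signal,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
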