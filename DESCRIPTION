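Package: fconnectome
Title: Graph-Theoretic Analysis of Resting-State Functional Connectomes
    with Psychometric Subtyping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for resting-state functional connectome
    analysis at the region-of-interest level: temporal cleaning of ROI
    time series (detrending, 24-parameter motion plus tissue nuisance
    regression, motion scrubbing, band-pass filtering), Pearson/Fisher-z
    connectivity matrices, proportional-sparsity binarization with
    group-occurrence averaging, global and nodal graph topology with
    degree-preserving random-network normalization and area-under-curve
    integration across thresholds, greedy-modularity community detection
    with module-level metrics, the network-based statistic
    (max-component permutation test), covariate-adjusted group inference
    with Bonferroni/FDR correction families, and unsupervised patient
    subtyping from psychometric scales with cluster-validity retesting.
    Includes a synthetic cohort generator emulating a three-group
    case-control resting-state study so the full pipeline is testable
    without access to subject-level imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    cluster,
    e1071,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    yaml
Config/testthat/edition: 3
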