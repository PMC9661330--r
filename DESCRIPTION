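Package: amypower
Title: Source-Level EEG Band-Power Analysis of Brain Amyloidosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Resting-state EEG pipeline for contrasting amyloid-positive and
    amyloid-negative elderly cohorts at the source level. Provides a synthetic
    cohort generator (three-shell spherical forward model, eyes-closed and
    eyes-open blocks, SUVr-coupled mid-frontal theta effect, ocular blinks,
    aberrant channels), sensor-space cleaning (zero-phase FIR filtering,
    z-score channel rejection, common-average re-referencing, fixed-point ICA
    blink removal), LCMV beamformer source projection with a common spatial
    filter over a seven-band filter bank, relative band-power maps with
    voxel-wise z-scoring and outlier-subject exclusion, and group statistics:
    cluster-based Monte-Carlo permutation tests with the max-sum statistic,
    bootstrap subsample reliability for unbalanced groups, SUVr vincentile
    ANOVA with Bonferroni correction, regression of power on memory scores,
    and amyloid-by-APOE analysis of covariance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    car,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
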