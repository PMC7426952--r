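Package: crossdyn
Title: Cross-Area Neural Population Dynamics from Paired Spike Recordings
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies shared (cross-area) and local population dynamics from
    simultaneously recorded spike trains in two cortical regions, such as rodent
    premotor (M2) and primary motor (M1) cortex during reach-to-grasp behavior.
    Provides spike binning and trial alignment, canonical correlation analysis
    (CCA) of paired populations with cross-validated R2 and trial-shuffle
    significance testing, weight-stability and bin-width/lag sweeps, projection
    onto the orthogonal complement of the cross-area subspace to obtain local
    dynamics with permutation tests for inter-area timing, a d-prime single-trial
    reach-modulation statistic and its relationship to reach duration, logistic
    regression detection of reach initiation with ROC/AUC, hierarchical bootstrap
    inference, factor-analysis shared-over-total variance, and an inhomogeneous
    Poisson session simulator with planted shared and local latents for
    ground-truth validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    yaml,
    glmnet,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    jsonlite,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
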