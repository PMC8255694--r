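Package: iccseg
Title: Deeply Supervised Volumetric Segmentation of the Intracranial Cavity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end intracranial-cavity (ICC) segmentation of whole-head
    T1-weighted MRI with a deeply supervised multi-resolution 3D convolutional
    network. Provides non-destructive preprocessing (auto-crop, zero-mean/unit-SD
    normalisation, stage-compatible padding) with exact restoration to native
    space, network construction for 2-5 resolution stages, training with
    round-robin cohort sampling, Nesterov-momentum SGD, exponential-moving-average
    weights and global-norm gradient clipping, probability-map inference with
    empirical threshold calibration, a segmentation-evaluation suite (Dice,
    Hausdorff distance in mm, false-negative/false-positive percentages, volume
    differences, longitudinal consistency), a synthetic multi-cohort head-phantom
    generator with analytic ground truth, and experiment harnesses for
    cohort-diversity and stage-count studies at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, Rcpp, RNifti, jsonlite
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
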