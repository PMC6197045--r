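Package: harcnn
Title: Child Physical-Activity Recognition from a Waist-Worn Tri-Axial
    Accelerometer with a 1-D Convolutional Network
Version: 0.1.0
Authors@R:
    person("harcnn", "maintainers", email = "harcnn@example.org",
           role = c("aut", "cre"))
Description: End-to-end pipeline for classifying ten child physical
    activities (slow/fast walking, slow/fast running, stairs up/down,
    jumping rope, standing up, sitting down, remaining still) from a
    single waist-worn tri-axial accelerometer sampled at 45.4 Hz.
    Provides zero-phase high-pass filtering, 128-sample window
    segmentation with 50 percent overlap, rotational data augmentation,
    a three-block 1-D convolutional network trained with SGD plus
    momentum and step learning-rate decay, block-wise k-fold
    cross-validation, confusion-matrix evaluation with class merging,
    conventional-classifier baselines (SVM, decision tree, k-NN) on a
    12-feature summary, and a seeded synthetic-cohort generator so the
    whole pipeline is testable without any data download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
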