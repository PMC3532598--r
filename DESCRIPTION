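Package: painscale
Title: Multivariate Decoding of Near-Threshold Pain Perception Across Spatial Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested implementation of a multivariate pattern analysis (MVPA)
    pipeline for decoding the subjective perception of near-threshold pain from
    volumetric fMRI time series. The pipeline estimates trial-wise activity
    patterns (beta series) with a first-level general linear model using
    canonical haemodynamic response convolution, discrete-cosine high-pass
    filtering and AR(1) prewhitening; classifies single trials with a linear
    soft-margin support vector machine under leave-one-session-out
    cross-validation with nested leave-one-trial-out selection of the
    regularization hyperparameter; performs permutation inference on decoding
    accuracies (within-session label shuffles) and on classifier weight maps
    (voxel-wise t-scores against permutation nulls with family-wise error
    correction); and compares decoding performance across spatial scales, from
    single voxels through anatomical regions of interest and their unions to
    the whole brain. A synthetic-data module generates multi-subject datasets
    with the serial-correlation and session structure the analysis assumes,
    including ground truth for recovery tests.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    nortest,
    stats,
    utils,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    e1071,
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
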