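Package: dbsfmri
Title: Autoencoder and MLP Models for fMRI-Guided Deep Brain Stimulation
    Programming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for optimizing deep brain stimulation (DBS) parameters from
    blood-oxygenation-level-dependent (BOLD) fMRI response maps. Provides a
    synthetic cohort simulator for parameter-dependent DBS-fMRI responses, GLM
    t-statistic mapping of block-design BOLD series (double-gamma hemodynamic
    response, motion censoring and regression, Gaussian smoothing), an
    unsupervised convolutional autoencoder trained with a structural-similarity
    (SSIM) reconstruction loss that compresses response maps to a compact
    latent code, multilayer-perceptron heads for optimal/non-optimal
    classification and stimulation-parameter regression with stratified k-fold
    cross-validation, evaluation metrics (ROC/PR curves, RMSE, tolerance
    accuracy, cosine similarity, t-SNE embedding), and a closed-loop
    semi-automated programming protocol simulator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    cluster,
    ggplot2,
    optparse
Config/testthat/edition: 3
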