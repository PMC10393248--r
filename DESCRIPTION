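Package: eegdyn
Title: Nonlinear EEG Dynamics and Supervised Tensor Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for discovering neurodynamic EEG biomarkers
    of childhood psychiatric outcomes. Decomposes multichannel resting-state
    EEG into canonical frequency bands with a Daubechies-4 discrete wavelet
    transform, computes twelve nonlinear dynamical measures per channel and
    band (sample entropy, correlation dimension, detrended fluctuation
    analysis, and nine recurrence-plot measures), organizes them into
    axis-labelled multiway tensors, fits a supervised canonical polyadic
    (SupCP) factorization by an EM algorithm with a marginal Gaussian
    likelihood, and evaluates probabilistic diagnosis classification and age
    regression with stratified cross-validation (AUROC, Brier score).
    Includes synthetic-data generators for supervised low-rank tensors and
    EEG-like cohorts with configurable age and group effects.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    pROC,
    caret,
    randomForest,
    e1071,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
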