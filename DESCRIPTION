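Package: eegtopoclass
Title: Topographic Image Sequence Classification of Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for two-class classification of resting-state
    multichannel EEG via topographic image sequences.  Band-decomposed sliding
    windows (theta/alpha/beta) are summarised per channel by fuzzy entropy or
    by mean FFT band amplitude, projected onto a 32x32 scalp image through
    azimuthal equidistant projection and piecewise-cubic Clough-Tocher
    interpolation, and classified with a time-distributed CNN + LSTM hybrid
    network trained by Adam, alongside SVM/KNN/logistic-regression baselines,
    a tenfold cross-validation harness, channel-wise Welch t maps with
    FDR/Bonferroni correction, and a seeded synthetic EEG cohort generator
    for desk-scale validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    data.table,
    glmnet,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
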