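Package: nirsdecode
Title: Simulation, Preprocessing, Channel-Wise GLM and Deep Decoding of
    Block-Design fNIRS Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for block-design functional near-infrared
    spectroscopy (fNIRS) emotion-decoding studies. Generates ground-truthed
    two-wavelength recordings (canonical double-gamma hemodynamic responses,
    physiological oscillations, drift, AR(1) plus white measurement noise and
    motion artifacts), converts optical density to oxy-/deoxy-hemoglobin via
    the modified Beer-Lambert law, performs moving-window spline motion
    correction, zero-phase band-stop and discrete-cosine-transform high-pass
    filtering, AR(1) pre-whitened channel-wise general linear models with
    max-statistic permutation family-wise error correction, builds labelled
    emotion-minus-neutral contrast matrices, and classifies them with a
    CNN-LSTM network implemented from first principles alongside SVM, CNN-only
    and LSTM-only baselines under a stratified split with five-fold
    cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
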