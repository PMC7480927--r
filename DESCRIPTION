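Package: neofba
Title: Functional Brain Age Estimation and Rater-Agreement Analysis for Preterm EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating functional brain age (FBA) from preterm
    neonatal EEG and for quantifying how well human raters and algorithms
    recover postmenstrual age (PMA). Includes a synthetic generator for
    discontinuous (burst-suppression) preterm EEG and rater panels, EDF
    input/output with neonatal bipolar montages and amplitude-integrated
    EEG (aEEG) traces, amplitude-based artefact masking and epoch
    segmentation, quantitative EEG features (range-EEG percentiles,
    inter-burst intervals, relative band powers, sample entropy,
    suppression curve, burst duration and shape statistics), support-vector
    regression of age with leave-one-infant-out cross-validation, and an
    agreement/accuracy layer: ICC(2,1) with closed-form and bootstrap
    confidence intervals, bootstrap comparison of panel ICCs,
    systematic/random error decomposition, Pitman-Morgan and Bartlett
    variance tests, per-infant trajectory analysis and Bonferroni-corrected
    subgroup comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    e1071,
    generics,
    ggplot2,
    purrr,
    Rcpp,
    rlang,
    scales,
    signal,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
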