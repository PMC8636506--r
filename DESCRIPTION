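Package: ebisah
Title: Early Brain Injury Volumetry and Cognitive Outcome Prediction in
    Good-Grade Subarachnoid Haemorrhage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for MRI markers of early brain injury after
    aneurysmal subarachnoid haemorrhage (SAH). Provides SIENAX-style global
    tissue volumetry from segmented fraction maps, voxel-based morphometry
    with threshold-free cluster enhancement (TFCE) and permutation-based
    family-wise-error correction, grey-matter apparent diffusion coefficient
    (ADC) summaries, a codified neurocognitive-impairment classifier
    (two-or-more domain deficits at the 5th percentile), and an ROI-based
    leave-one-out cross-validated threshold classifier with ROC/AUC and
    effect-size reporting for predicting 3-month cognitive impairment from
    acute-phase scans. A synthetic-data module generates phantom image
    cohorts and tabular cohorts with the statistical structure the analyses
    assume, so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    tibble,
    tidyr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    jsonlite,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
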