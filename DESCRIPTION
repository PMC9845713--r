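Package: neohrv
Title: Heart Rate Variability Modelling of Early EEG Severity in Neonatal
    Encephalopathy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting the severity of the
    electroencephalographic (EEG) background in neonatal hypoxic-ischaemic
    encephalopathy from early heart rate variability (HRV). Provides R-peak
    detection and automated artifact rules for neonatal ECG/RR series,
    segmentation of one-hour epochs into overlapping five-minute windows,
    time-domain (mean NN, SDNN, TINN), frequency-domain (VLF/LF/HF band
    powers from a Welch periodogram of the resampled tachogram) and
    complexity (moving-average multiscale sample entropy) features,
    feature standardization, univariable screening with correlation
    pruning, multivariable logistic risk models with AUROC, Youden
    operating points and Hosmer-Lemeshow calibration, transcriptions of
    published model equations, and a synthetic two-group cohort generator
    for end-to-end testing when clinical recordings are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    graphics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
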