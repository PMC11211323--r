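Package: deeprisk
Title: Multimodal Arrhythmic Risk Prediction from Cardiac MRI, ECG and
    Clinical Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for building and evaluating multimodal one-year
    ventricular-arrhythmia risk models in non-ischaemic cardiomyopathy.
    Provides a synthetic cohort generator (12-lead ECGs, short-axis
    late-gadolinium-enhancement volumes, clinical tables and outcomes with
    known effect sizes), signal and image preprocessing (mean P-QRS-T beat
    extraction, myocardium masking to a 12x64x64x2 model input), residual
    beta-variational autoencoders for latent feature extraction, a
    SMOTE-balanced gradient-boosted risk classifier with surrogate-guided
    hyperparameter search, latent-space explainability (Shapley
    attributions, latent traversal, gradient attention maps), and the full
    evaluation stack (ROC/PR analysis, bootstrap confidence intervals,
    DeLong comparison, Youden cut-points, calibration).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    ranger,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    broom,
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
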