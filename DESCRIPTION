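Package: gliomix
Title: Integrated Qualitative and Quantitative MRI Analysis for Glioblastoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, reproducible pipeline for combined qualitative
    (VASARI-coded) and quantitative (radiomics) MRI analysis in glioblastoma.
    Provides a synthetic multi-scanner cohort generator with known ground
    truth, MRI preprocessing (resampling, bias-field correction, histogram
    equalization, frozen Z-score transfer), from-scratch radiomics feature
    extraction (first-order, shape, GLCM/GLRLM/GLSZM/GLDM/NGTDM texture
    classes over original, Laplacian-of-Gaussian and wavelet filtered
    images), Cox prognostic-index stacking with external-validation
    diagnostics (Harrell's C, calibration slope, misspecification test,
    risk-group Kaplan-Meier splits), and molecular-marker classification via
    randomized hyperparameter search with repeated-split evaluation,
    probability-averaging ensembles and bootstrap AUC confidence intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    survival,
    igraph,
    ranger,
    xgboost,
    glmnet,
    jsonlite,
    yaml,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
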