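Package: perirad
Title: Peritumoral CT Radiomics Pipeline for NSCLC Recurrence Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for predicting non-small cell lung cancer
    recurrence from pre-treatment CT images and clinical covariates. Builds
    square tumor crops at several peritumoral dilations from segmented CT
    stacks, extracts pooling-layer texture features with a declared feature
    extractor, selects stable features by AUC-exceedance frequency over
    repeated stratified cross-validation, imputes missing clinical data with
    an iterative random-forest scheme, and evaluates a linear support vector
    machine with Youden-index thresholded metrics on a stratified hold-out
    split. Ships a synthetic cohort generator that plants recurrence signal
    in a peritumoral texture annulus and in clinical covariates so the whole
    pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    randomForest,
    jsonlite,
    png,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    knitr
Config/testthat/edition: 3
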