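Package: lnrpv
Title: Large-Nodule Radiomics Signature and Clinical Decision Support
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Development, scoring and evaluation of a two-feature CT
    radiomics signature (surface-to-volume ratio and grey-level
    co-occurrence matrix correlation) for malignancy risk in large
    (15-30 mm) lung nodules, together with the Brock and Herder clinical
    risk calculators and a decision-support rule that upgrades high-risk
    nodules within the intermediate (10-70%) Herder band. Includes NIfTI
    preprocessing (resampling, intensity capping, cropping), synthetic
    phantom and cohort generators with analytically known properties,
    LASSO-based signature development with grouped stratified splitting
    and univariable screening, and the evaluation statistics used in
    nodule-classification studies (bootstrap ROC/AUC, Youden cutpoints,
    DeLong tests, agreement ICC, Kruskal-Wallis, Dice).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    glmnet,
    e1071,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
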