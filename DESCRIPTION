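Package: octarep
Title: Repeatability and Discrimination Analysis of OCTA Image Binarization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies macular optical coherence tomography angiography (OCTA)
    en-face images with seven binarization approaches (a manual threshold based
    on the maximum grey value inside the foveal avascular zone, plus the Huang,
    Li, Otsu, Moments, Mean and Percentile histogram algorithms), computes
    vessel density and vessel skeleton density from the binarized and
    skeletonized maps, and runs the full test-retest repeatability and
    healthy-versus-pathology discrimination battery: relative differences,
    intraclass correlation coefficients, repeatability coefficients, Friedman
    and Wilcoxon tests with Holm-Bonferroni correction, age-adjusted linear
    regression, Friedman power simulation, and age-adjusted logistic
    regression with ROC/AUC comparison. Includes a synthetic-angiogram
    generator producing paired test-retest cohorts with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    png,
    jsonlite,
    mgcv,
    EBImage,
    pROC,
    glmnet,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
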