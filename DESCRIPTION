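Package: rectexture
Title: First-Order MRI Texture Analysis for Rectal Cancer Treatment-Response
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for first-order (histogram) texture
    analysis of single-slice T2-weighted MRI tumor regions of interest in
    locally advanced rectal cancer treated with neoadjuvant
    chemoradiotherapy. Extracts seven first-order features (mean, standard
    deviation, skewness, kurtosis, uniformity, energy, entropy) from masked
    2D images after equal-width intensity discretization, quantifies
    two-rater interobserver agreement with intraclass correlation
    coefficients, compares pre-treatment against early-treatment scans
    (Wilcoxon signed-rank) and responders against nonresponders
    (Mann-Whitney) under tumor-regression-grade and
    pathological-complete-response reference standards, and evaluates
    response prediction with ROC analysis, Youden-index cutoffs, and
    backward-elimination logistic combination of features. Includes a
    reproducible synthetic phantom cohort generator with controllable
    first-order statistics, two raters and two timepoints, for method
    validation when patient images are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    RNifti,
    ggplot2,
    jsonlite,
    pROC,
    stats,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
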