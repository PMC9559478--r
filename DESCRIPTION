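Package: grazemilk
Title: Detecting Grass-Based Dairy Feeding from Milk Composition Traits
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to classify herd bulk-milk records as produced under a
    grass-based diet or not, when no grazing calendars exist, using the
    calendar month of milk testing as an indirect label. Implements
    two-class partial least squares discriminant analysis (NIPALS) with
    cross-validated latent-variable selection capped at 30 components,
    logistic calibration of class probabilities, Variable Importance in
    Projection (VIP) scores and VIP-threshold predictor reduction,
    stratified k-fold cross-validation with ROC/AUC and confusion metrics,
    a month-restricted external validation protocol, temperature-humidity
    index (THI) linkage of monthly probability curves to meteorology, and
    Ward.D2 hierarchical clustering of farm-by-year monthly probability
    profiles into feeding typologies (intensive, extensive, intermediate,
    with skimmed-milk cluster flagging). A seeded synthetic-data module
    simulates meteorology, latent grass fractions, and herd bulk-milk
    records for 48 mid-infrared-predicted composition traits so the whole
    pipeline is testable without proprietary milk-recording data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pROC,
    jsonlite,
    withr
Config/testthat/edition: 3
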