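Package: oniondx
Title: Compositional Nutrient Diagnosis and Machine-Learning Yield Modelling
    for Onion Fertilizer Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for feature-based nutrient management of onion (Allium cepa)
    from multi-environment fertilizer trials. Implements centered log-ratio
    (clr) compositional analysis of tissue ionomes with a filling value,
    cultivar-specific tissue nutrient standards with confidence intervals and
    back-transformed centroids, clr-based nutrient balance indices and
    nearest-neighbour diagnosis, agro-climatic feature engineering (rainfall
    Shannon diversity index, degree-days, soil exchangeable acidity, CEC and
    base saturation), RReliefF and gain-ratio feature relevance ranking,
    random-forest imputation of missing trial data, and repeated stratified
    evaluation of random-forest and gradient-boosting models for bulb yield
    regression and balance classification with confusion-quadrant specimen
    selection. A synthetic multi-trial generator emulates the statistical
    structure of the trial data so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ranger,
    xgboost,
    pROC,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
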