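Package: sdmrisk
Title: Presence-Only Ensemble Species Distribution Models and
    Multi-Species Envenoming Risk Surfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for presence-only ensemble habitat
    suitability modelling and multiplicative multi-species risk mapping,
    from predictor screening (variance inflation factors, topographic
    heterogeneity) through five base learners (GLM, GAM, gradient
    boosting, random forest, and a MaxEnt-style penalized logistic
    model), threshold-based evaluation (AUC, true skill statistic,
    continuous Boyce index, maxSSS), permutation variable importance,
    ensemble combination, multiplicative risk surfaces, and settlement
    exposure tabulation.  Includes a virtual-species simulator that
    generates spatially autocorrelated, mutually correlated
    environmental landscapes with known suitability truth, so the whole
    pipeline is testable by parameter and surface recovery without any
    external rasters.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    mgcv,
    randomForest,
    xgboost,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
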