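Package: vuspanel
Title: Three-Class ROC Analysis and Non-Inferiority Testing of Biomarker Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating diagnostic marker panels across three ordered
    disease classes. Implements the nonparametric volume under the ROC surface
    (VUS) with stratified bootstrap confidence intervals and empirical ROC
    surface grids, Bayesian model averaging of multinomial logistic models via
    the Begg-Gray binary decomposition, CAR-score (correlation-adjusted marginal
    correlation) panel construction, and bootstrap non-inferiority and
    superiority testing of panel predictors against a reference marker.
    Includes a synthetic cohort generator (Gaussian copula with class-dependent
    latent shifts), reference-marker multiple imputation, Yeo-Johnson
    transformation, correlation-matrix PCA, and the univariate test battery
    (Anderson-Darling, Fligner-Killeen, Games-Howell, Kendall tau with Hochberg
    adjustment) used in serum amino-acid biomarker studies of pancreatic
    carcinoma versus pancreatitis versus healthy controls.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nortest,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0),
    nnet,
    car,
    optparse
Config/testthat/edition: 3
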