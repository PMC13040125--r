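Package: usradiomics
Title: Ultrasound Radiomics Modeling for Uterine Sarcoma Risk
Version: 0.1.0
Authors@R:
    person("US", "Radiomics Maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: A tested re-implementation of a grayscale-ultrasound radiomics
    pipeline for discriminating uterine sarcomas from usual-type leiomyomas.
    Provides speckle denoising (adaptive Wiener filter), within-ROI z-score
    normalization and fixed-bin-number gray-level discretization; first-order
    and GLCM/GLRLM/GLSZM texture features; false-discovery-rate univariate
    feature selection with iterative Spearman correlation pruning; Boruta and
    stepwise-AIC selection for the tumor/myometrium delta-radiomics subanalysis;
    four classifier families (logistic regression, random forest, RBF support
    vector machine, gradient-boosted trees) with randomized 5-fold
    cross-validated hyperparameter search; Youden-cutoff classification metrics
    with bootstrap and normal-approximation confidence intervals, Cohen's kappa,
    and logistic-recalibration calibration analysis. A seeded synthetic-cohort
    generator emulates the case-control imaging study so the whole pipeline is
    testable without access to patient images.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
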