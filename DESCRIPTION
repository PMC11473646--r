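Package: torsadex
Title: In Silico Cardiac Drug Toxicity Pipeline with Shapley-Based
    Biomarker Attribution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A CiPA-style pipeline for torsades de pointes (TdP) risk
    assessment of drugs. Fits Hill dose-response curves to ion-channel
    block data by adaptive Markov chain Monte Carlo, paces a reduced
    ventricular myocyte model under per-channel conductance block,
    extracts twelve action-potential and calcium-transient biomarkers
    (including qNet and qInward), trains six classifier families by
    stratified grid-search cross-validation, attributes predictions to
    biomarkers with exact or permutation-sampled Shapley values, performs
    Shapley-guided one-by-one feature elimination, and evaluates
    three-class TdP risk classification with bootstrap drug sets
    (accuracy, one-vs-rest AUC, likelihood ratios with percentile
    confidence intervals). Synthetic data generators with known ground
    truth make every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    jsonlite,
    yaml,
    MASS,
    nnet,
    ranger,
    xgboost,
    e1071,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'torsadex-package.R'
    'AllClasses.R'
    'ionic-model.R'
    'pacing.R'
    'biomarkers.R'
    'mlp.R'
    'classifiers.R'
    'evaluation.R'
    'shap.R'
    'elimination.R'
    'hill.R'
    'synthetic.R'
    'pipeline.R'
    'utils.R'
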