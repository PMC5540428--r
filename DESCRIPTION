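Package: twinirt
Title: Nonparametric Item Response Theory and Twin Modelling for Questionnaire Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for validating polytomous mental-health
    questionnaire scales in twin-family cohorts. Implements kernel-smoothed
    nonparametric item response theory (option characteristic curves, item
    response step functions with confidence bands, maximum-likelihood latent
    scoring, expected-score principal components for difficulty and
    discrimination), differential item functioning screening, an iterative
    scale-refinement protocol, classical psychometrics (Cronbach's alpha,
    polytomous Loevinger scalability with Mokken classification, two-way
    consistency intraclass correlation), pedigree utilities (relatedness
    matrices, demographic-matched familial pruning, age binning), twin
    ACE/ADE variance-component models fitted by full-information maximum
    likelihood with bivariate Cholesky genetic correlations, and
    kinship-aware penalized quasi-likelihood logistic association of scale
    scores with binary diagnoses. A synthetic twin-cohort generator with
    graded-response items reproduces the data structures every stage
    assumes, so the whole pipeline is testable without access to any
    participant data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
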