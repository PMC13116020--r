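Package: twingem
Title: Twin Models for Gene-Environment Interplay Between Neighbourhood
    Walkability and Body Mass Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classical twin-design analysis of the interplay between a
    residential environmental exposure (a walkability index) and body mass
    index. Provides a twin-cohort data model with CSV ingestion, median
    imputation of covariates and age/sex residualization; individual-level
    regression with pair-clustered sandwich standard errors and the
    monozygotic co-twin-control (within-pair difference) regression;
    intraclass correlations, Falconer decomposition and full-information
    maximum-likelihood fitting of ACE/ADE-family univariate twin models with
    saturated-model assumption tests; and a bivariate Cholesky moderation
    model in which the exposure, entered per twin as a definition variable,
    moderates the genetic and environmental paths to BMI, with variance
    profiles over the moderator. A synthetic twin-cohort generator reproduces
    the statistical structure each stage assumes so that every fit is
    testable by simulation recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    sandwich,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
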