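Package: biometwin
Title: Biometrical Twin Models for Continuous Traits, Extremes and
    Diagnoses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Classical twin-design analyses for a continuous phenotype and
    binary diagnoses: maximum-likelihood ACE-family variance decomposition
    with saturated-model assumption tests and profile-likelihood
    confidence intervals; DeFries-Fulker extremes analysis (classical
    double-entered regression and a model-fitting implementation);
    liability-threshold models with tetrachoric twin correlations and
    probandwise concordance; and joint categorical-continuous bivariate
    models yielding genetic and non-shared environmental cross-trait
    correlations and bivariate heritability. Includes a synthetic
    twin-cohort generator with known ground truth for testing every
    estimation stage, phenotype construction (questionnaire scoring with
    missingness rules, multi-source case classification), model
    comparison by likelihood-ratio tests and information criteria, and a
    pipeline running the full workflow.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    sandwich
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
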