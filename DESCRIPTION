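Package: mvcjs
Title: Multistate Hidden-Markov Mark-Recapture Models of Pinniped Reproduction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Multivariate-state Cormack-Jolly-Seber models for longitudinal
    resighting data on marked female pinnipeds, formulated as a hidden Markov
    process over reproductive state (Prebreeder, With-Pup, With-Juvenile,
    No-Dependent) crossed with location stratum (rookery, haulout).  Provides
    capture-history encoding from dated sighting records on a mixed occasion
    structure (annual pooled occasions plus within-year robust-design
    occasions), forward-algorithm maximum likelihood with structural zeros and
    fixed parameters, AIC model selection, derived age-specific
    reproductive-state proportions with a neonatal-mortality correction,
    multivariate-normal parametric bootstrap intervals, deterministic Leslie
    matrix projection with delta-method confidence intervals, and a full
    generative simulator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    MASS,
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
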