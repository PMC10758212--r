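Package: pedblup
Title: Pedigree-Based Animal Models with Common-Litter Effects
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genetic evaluation of swine production and body-size traits with
    pedigree-based linear mixed ("animal") models. Builds the numerator
    relationship matrix and its sparse inverse from a pedigree (Henderson's
    rules with inbreeding from the Meuwissen-Luo algorithm), estimates
    variance components by restricted maximum likelihood through the sparse
    mixed-model equations for single-trait and bivariate models with and
    without a common-litter random effect, derives heritabilities,
    litter-effect ratios and genetic/phenotypic correlations with
    delta-method standard errors, compares model fit by AIC, and computes
    estimated breeding values and genetic trends by birth year. Includes a
    multi-generation herd simulator that generates pedigrees and phenotypes
    under the same generative model, so the whole pipeline is testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    car
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
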