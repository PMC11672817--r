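Package: daysopen
Title: Genetic Evaluation of Days Open with Censored Records
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Pedigree-based Bayesian genetic evaluation of days open (the
    interval from calving to subsequent conception) in dairy cattle when a
    fraction of the records is right-censored. Provides pedigree algebra
    (inbreeding, numerator relationship matrix and its sparse inverse),
    herd-year-season data editing, Henderson's mixed-model equations, Gibbs
    samplers for a repeatability animal model and for a bivariate
    threshold-linear model with a latent censorship liability, three
    censoring treatments (dropping censored records, penalty imputation,
    and the penalized threshold model), LR-method cross-validation of
    estimated breeding values, and a synthetic-data generator with known
    ground truth for testing the whole pipeline.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
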