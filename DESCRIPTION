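Package: evodecomp
Title: Decomposing Phenotypic Trends in Wild Pedigreed Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Quantitative-genetic decomposition of long-term phenotypic change in
    wild pedigreed populations, built around the red deer parturition-date system.
    Provides pedigree utilities (additive relationship matrix, inbreeding
    coefficients, genetic-group ancestry proportions, gene dropping), a Gibbs
    sampler for Gaussian and overdispersed-Poisson animal models with
    pedigree-structured random effects, selection differentials and gradients
    with univariate and multivariate breeder's-equation predictions, three
    estimators of realized genetic change (conservative and non-conservative
    regressions of predicted breeding values on time, and the secondary theorem
    of selection), a gene-dropping drift null, Geber decomposition of the
    phenotypic trend into covariate contributions, and a synthetic-population
    simulator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    mgcv,
    methods,
    graphics,
    grDevices,
    stats,
    utils
Suggests:
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
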