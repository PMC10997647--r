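Package: vrpgls
Title: Variable-Rates Bayesian Phylogenetic Regression for Macroecological Rules
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Bayesian phylogenetic generalised least squares regression with
    reversible-jump variable rates of trait evolution, for testing
    macroecological hypotheses such as Bergmann's rule on time-calibrated
    phylogenies. Includes Pagel's lambda and branch/clade rate-scalar
    covariance models, a Metropolis-Hastings/reversible-jump sampler that
    resamples linked occurrence records for species known from multiple
    localities, stepping-stone marginal-likelihood estimation with Bayes
    factor model selection, branch-wise ancestral change (contrast)
    pipelines, latitudinal-zone fossil sampling-bias covariates, and
    seeded synthetic-data generators for positive and negative controls.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ape,
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    phytools,
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
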