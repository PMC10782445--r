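Package: redoxcb
Title: Redox Potentials from Nonequilibrium Work Values via Crooks-Bayes
    Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Estimates protein reduction free energies and redox midpoint
    potentials from paired oxidized/reduced snapshot energies produced by
    molecular dynamics simulations. Work values for instantaneous reduction
    and oxidation are combined through the Crooks fluctuation relation with
    a Bayesian logistic-likelihood posterior (the Crooks-Bayes estimator),
    alongside the Bennett acceptance ratio, Jarzynski/free-energy
    perturbation, linear-response and histogram-crossing estimators.
    Includes a one-electron Nernst fitter for spectroelectrochemical
    titration curves, Crooks-consistent synthetic data generators with
    analytic ground truth, redox-shift tables with error propagation, and
    correlation benchmarking against experimental values.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
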