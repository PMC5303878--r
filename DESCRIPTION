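Package: t6phase
Title: Phase Separation by Contact-Dependent Killing in Dense Bacterial Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators and spatial statistics for studying how contact-dependent
    killing (for example by the type VI secretion system, T6SS) drives an initially
    well-mixed two-strain bacterial population to phase separate into growing clonal
    domains. Provides an individual-based lattice model of mutual killing and
    reproduction, a stochastic Ising spin model as the statistical-mechanics
    reference for non-conserved (Model A) coarsening, and a two-strain
    reaction-diffusion model with an optional diffusible public good. Analysis tools
    include the radially averaged structure factor S(q) with peak extraction,
    coarsening-scaling fits and dynamic-scaling collapse, the kin assortment
    statistic r(h), well-mixed equilibrium and stability analysis, linear
    perturbation-growth experiments, and cooperator-versus-cheat invasion scenarios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tools,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    png,
    deSolve
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
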