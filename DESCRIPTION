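Package: noisyvoter
Title: The Noisy Voter Model on Complex Networks: Simulation, Annealed
    Theory and Heterogeneity Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for the noisy voter (Kirman herding) model on complex
    networks. Generates the standard uncorrelated network ensembles
    (Erdos-Renyi, Barabasi-Albert, dichotomous, random-regular, complete,
    2D lattice), simulates the continuous-time dynamics exactly with an
    event-driven Gillespie algorithm, and evaluates annealed-approximation
    closed forms for the stationary variance of the aggregate state, the
    noise-induced bimodal-unimodal finite-size transition and its
    heterogeneity-dependent critical point, the stationary interface
    density, and the two-exponential stationary autocorrelation. Includes
    exact master-equation solvers for small systems, estimators for
    simulated trajectories, and inference of the model rates and of the
    network degree heterogeneity from the aggregate autocorrelation alone.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    Matrix,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
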