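Package: ratepaths
Title: Transition Rates of Two-State Systems by Committor Flux, Spectral
    Analysis, and Reactive-Flux Correlation Functions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes transition rates of bistable one-dimensional stochastic
    systems three consistent ways: committor-based transition-path-theory
    reactive flux by quadrature, spectral decomposition of a discretized
    Markov propagator, and activated-dynamics correlation-function
    estimators (indicator, position, committor, and indicator-restricted
    committor correlators) evaluated on Brownian or Langevin trajectories
    generated by built-in integrators. Ships three double-well benchmark
    potentials with narrow, medium, and broad free-energy barriers as fully
    reproducible test systems.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
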