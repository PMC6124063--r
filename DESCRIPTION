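Package: auxregion
Title: Auxiliary-Region Hybrid Coupling of PDE and Brownian Dynamics for
    Reaction-Diffusion Systems
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Event-driven hybrid simulation of stochastic reaction-diffusion
    systems in which a deterministic partial differential equation (PDE)
    regime is coupled to an individual-based Brownian-dynamics regime
    through two interface-adjacent auxiliary regions evolved as a
    two-compartment jump process by the Gillespie stochastic simulation
    algorithm.  Includes a theta-method finite-difference PDE solver with
    conservative zero-flux and prescribed-flux boundaries, Brownian updates
    with reflective boundaries, microscopic reactions up to second order
    via the lambda-rho scheme with deterministic rate calibration, an
    adaptive (threshold-driven) interface, mean-field and two-compartment
    reference oracles, and an error-analysis toolkit (histogram distance
    error, region relative errors, binned variance, time-step/region-width
    robustness sweeps).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    graphics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
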