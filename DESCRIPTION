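Package: reintro
Title: Minimum-Cost Species Reintroduction in a Two-Sex Reaction-Diffusion Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for planning the spatial release of a reintroduced species
    whose dynamics follow a one-dimensional two-sex reaction-diffusion model
    with a strong Allee effect. Provides closed-form analysis of the local
    (non-spatial) dynamics including the density-maximizing sex ratio at
    birth, an explicit-Euler finite-difference integrator for the coupled
    female/male densities, phase-plane construction of the unstable aperiodic
    stationary profile (critical nucleus) of the symmetric single-sex
    reduction, binary-search determination of critical cluster lengths and
    densities for rectangular release designs, unit-step descent over
    sex-specific cluster lengths, and simulated annealing over arbitrary
    discretized release shapes under the constraint of assured restoration.
    Restoration cost is the total number of individuals released; all methods
    minimize it and can be compared on a common parameter set.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
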