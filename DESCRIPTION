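Package: tcellosc
Title: Competing Calcium Oscillation Mechanisms in T Lymphocytes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and numerical bifurcation analysis of a five-variable
    ordinary differential equation model of cytosolic calcium dynamics in
    T lymphocytes, in which store-operated calcium entry through the CRAC
    (STIM-Orai) channel competes with IP3-receptor-mediated calcium-induced
    calcium release. Provides the open-cell and reduced closed-cell models,
    stiff-capable integration, equilibrium computation, limit-cycle feature
    extraction with regime classification, pseudo-arclength continuation of
    equilibria with Hopf and fold detection, multiple-shooting continuation
    of periodic orbits with Floquet multipliers and detection of folds of
    cycles, period doublings and torus bifurcations, two-parameter
    continuation of Hopf curves, and scripted reproduction of the model's
    oscillation regimes and bifurcation sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
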