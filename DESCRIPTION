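Package: chlorodyn
Title: Chloride and Potassium Ion Dynamics in a Conductance-Based Neuron Model
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Single-compartment Hodgkin-Huxley-type neuron model in which the
    membrane potential is coupled to dynamic intracellular chloride and sodium
    and extracellular potassium concentrations, with KCC2 and NKCC1
    cotransporters, a Na+/K+ pump, GABA-A receptor input carrying both
    chloride and bicarbonate, and first-order potassium exchange with a bath.
    Provides a compiled fixed-step Runge-Kutta integrator, spike detection and
    firing-pattern classification (resting, tonic firing, periodic bursting,
    depolarization block), Newton-based fixed-point solves with Jacobian
    eigenvalue stability analysis, branch continuation with saddle-node and
    Hopf bifurcation detection, and scenario presets for the stimulation
    protocols used to study GABA-induced seizure-like events.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    deSolve,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
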