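Package: chargediff
Title: Charge-Difference Simulation of Neuronal Ionic Homeostasis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Discrete-time "charge-difference" simulation of cellular ionic
    homeostasis: coupled dynamics of intracellular Na+, K+ and Cl-
    concentrations, membrane potential, effective water volume and ATP
    expenditure under linear conductive leaks, an Na+/K+-ATPase of arbitrary
    stoichiometry, Na+,K+,2Cl- and K+,Cl- cotransporters, finite membrane
    water permeability and scheduled osmolyte buildups.  Membrane potential
    is never computed from an electroneutrality assumption; it is tracked
    incrementally from the net transferred charge divided by the membrane
    capacitance.  The package also provides the analytic equilibrium layer
    (Donnan and Double Donnan products, chord-conductance and pump voltages,
    osmolarity-charge asymmetry theory), a registry of ready-made simulation
    scenarios, steady-state sweep and rate-finding drivers, and a small
    command-line interface with JSON configuration files and CSV output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
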