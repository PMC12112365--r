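Package: cardiosim
Title: Closed-Loop Lumped-Parameter Cardiovascular Simulation and
    Pressure-Volume Loop Analysis
Version: 0.1.0
Authors@R:
    person("cardiosim", "developers", email = "cardiosim@example.org",
           role = c("aut", "cre"))
Description: A closed-loop lumped-parameter model of the human circulation
    built from time-varying elastance heart chambers and a multi-compartment
    arterial Windkessel, with a simulated vena-caval-occlusion (VCO)
    protocol, a vascular-aging parameter sweep, and a complete
    pressure-volume loop analysis suite: per-beat loop metrics, the four
    load-varying contractility relations (ESPVR, PRSW, dP/dtmax-EDV,
    EDV-PVA), pressure-work-index myocardial oxygen consumption, and
    mechanical versus myocardial efficiency. Includes a synthetic beat
    generator so the analysis stack is testable independently of the ODE
    core, CSV/JSON import and export, and a command-line driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
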