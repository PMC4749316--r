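Package: aviflow
Title: Lumped-Parameter Model of Unidirectional Airflow in Avian Lungs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates airflow through the avian respiratory system with a
    two-compartment lumped-parameter model in which the caudal and cranial
    airsacs act as elastic bellows and aerodynamic valving is represented by
    flow-direction-dependent (switched) airway resistances.  The switched
    linear system is integrated exactly within each flow regime and
    resistance switches are located by event detection on the zero crossings
    of the branch flows.  The package provides phase-plane eigen-analysis of
    the frozen-regime system, certificates for unidirectional parabronchial
    flow, breath-cycle metrics (tidal volume, ventilation efficiency,
    valving efficacies, inspiratory:expiratory ratios), parameter sweeps,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    deSolve,
    pracma
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
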