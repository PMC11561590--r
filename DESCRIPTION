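Package: cryoskin
Title: Coupled Phase-Change Heat Transfer and Thermo-Viscoelastic Stress
    Modelling for Tissue Cryopreservation
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulates controlled-rate cooling and water-bath rewarming of a
    skin sample immersed in cryoprotectant solution: transient 2D heat
    conduction with a smoothed (apparent heat capacity) liquid/ice phase
    change on a structured grid, one-way coupled to a quasi-static Maxwell
    thermo-viscoelastic stress solver with phase-change eigenstrain.  Also
    provides the companion bench-data computations of cryopreservation
    studies (cryoprotectant permeation kinetics from osmometry, differential
    scanning calorimetry melting-enthalpy and nonfreezing-water analysis,
    supercooling/recalescence event detection on thermocouple traces) and
    seeded synthetic-data generators with ground truth so every stage is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
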