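Package: massdyn
Title: Two-Compartment Energy-Balance Simulation of Body-Mass Dynamics
    with Social Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Daily-step simulation of individual body-mass dynamics from the
    energy balance between caloric intake and total energy expenditure. Body
    mass is partitioned into fat and lean compartments with fixed energy
    densities; the daily energy imbalance is routed between them either by the
    Forbes companionship relation or by a first-difference (Hall-type) mass
    ratio. Caloric intake follows the body mass through a per-individual
    responsiveness exponent, and expenditure decomposes into basal metabolism
    (FAO/WHO/UNU weight-based equations), diet-induced thermogenesis and a
    mass-proportional activity cost calibrated from the initial conditions.
    Stochastic social-interaction perturbations (social proximity times social
    influence) can be added to the daily balance. Includes a synthetic
    population generator, scenario presets with parameter sweeps, trajectory
    CSV/JSON output and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
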