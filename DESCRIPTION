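Package: modpolypill
Title: Cost-Effectiveness Modelling, Quality Control and Dose Titration for Modular Polypills
Version: 0.1.0
Authors@R: person("Modular Polypill", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: A discrete-time Markov cohort engine with discounting and
    half-cycle correction, cost-effectiveness analytics (incremental
    cost-effectiveness ratios, strict and extended dominance, efficiency
    frontier, one-way sensitivity and threshold search), a three-arm
    cardiovascular polypill model (standard care, fixed-dose combination,
    and variable-dose modular polypill), pharmacopeial quality-control
    calculators (content-uniformity acceptance value, weight variation,
    friability, disintegration, dissolution Q-criteria, hardness summary),
    exact integer dose-titration of modular tablet units under capsule and
    rod capacity constraints, and seeded synthetic-data generators with a
    micro-simulation oracle for validating the cohort engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
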