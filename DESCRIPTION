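Package: ventcontrol
Title: Steady-State Ventilatory Control Modelling and Ratio-of-Means
    Meta-Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Closed-form steady-state model of the chemoreflex control of
    breathing: the isometabolic (metabolic) hyperbola, the chemosensitivity
    line, their eupneic intersection, and the derived plant gain, loop gain,
    CO2 reserve and ventilatory reserve. Simulates acetazolamide-style
    interventions (left shift of the apnea threshold with optional changes
    in CO2 production and controller gain), reports percent changes in all
    derived quantities, and sweeps baseline conditions to map the relative
    reduction in loop gain. Also provides a ratio-of-means random-effects
    meta-analysis engine (delta-method variances, DerSimonian-Laird tau^2,
    Cochran's Q and I^2, weighted control statistics, implied mean
    differences, meta-regression, leave-one-out sensitivity, standardized
    mean differences) together with a seeded synthetic study-summary
    generator for calibration experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
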