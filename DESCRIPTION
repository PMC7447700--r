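Package: ricephys
Title: Leaf and Canopy Photosynthesis, Grain Filling and Cultivar Trait
    Analysis for Rice Field Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits leaf gas-exchange models (non-rectangular hyperbola light
    response; Farquhar-von Caemmerer-Berry A/Ci curves with Rubisco- and
    RuBP-regeneration-limited states), Richards growth curves for grain
    filling, and SPAD-to-chlorophyll calibrations; estimates canopy net CO2
    exchange from closed-chamber drawdown logs; and provides the cultivar
    comparison layer used in multi-year rice field trials (percent
    differences, two-sample t-tests, balanced two-way ANOVA with LSD letter
    groupings, and agronomic indices). Includes seeded synthetic-data
    generators for every input so the full pipeline is testable without
    field measurements.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
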