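Package: metapanel
Title: Multiplexed Colorimetric Metabolite-Panel Analysis Pipeline
Version: 0.1.0
Authors@R: person("Panel", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis pipeline for a multiplexed enzymatic
    colorimetric metabolite panel read out by a photodiode array: a seeded
    simulator of photodiode frame stacks (Michaelis-Menten product formation,
    Beer-Lambert photometry, sensor drift, noise and quantization), signal
    processing from raw frames to initial reaction rates (zero-phase
    Butterworth filtering, bad-sensor exclusion, spatial and temporal
    averaging, double-exponential fitting), Michaelis-Menten and linear
    calibration with IUPAC detection limits, standard-addition quantification
    of plasma metabolites, cohort-level univariate statistics, and a
    cross-validated random-forest panel classifier with pooled ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
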