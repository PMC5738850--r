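Package: gpasim
Title: Deterministic Genomic Prediction Accuracy Simulation
Version: 0.1.0
Authors@R:
    person("gpasim", "maintainers", email = "gpasim@example.org", role = c("aut", "cre"))
Description: Closed-form simulators for the expected accuracy of genomic
    prediction. Implements eight deterministic formulas relating prediction
    accuracy to training-population size, heritability, the effective number
    of independent chromosome segments, effective population size, marker
    number and marker-QTL linkage, including a two-training-population
    selection-index formula. Also provides a seeded genotype simulator and a
    ridge-regression estimator of the expectation term that links marker data
    to the effective number of chromosome segments, a declarative parameter
    sweep engine producing tidy accuracy tables, curve and surface rendering,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    withr,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
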