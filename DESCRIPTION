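Package: sporeflux
Title: Enumeration and Burial Budgeting of Thermophilic Fermentative Endospores
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies dormant thermophilic fermentative endospores (TFEs) in
    marine sediment and seawater from germination experiments. Implements
    growth-kinetics-based enumeration from incubation time courses (onset
    detection, anchored exponential fits, cell-specific rate calibration),
    maximum-likelihood most-probable-number (MPN) estimation with
    profile-likelihood confidence intervals, dipicolinic-acid (DPA)
    standard-addition quantification with conversion to spore counts, and a
    burial-decay / deposition-flux budget (first-order decay of abundance
    with sediment age, sedimentation-rate flux arithmetic, water-column
    supply). Includes seeded synthetic-data generators that emulate every
    input table the pipeline consumes, so all stages are testable without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
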