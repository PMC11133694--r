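Package: energyscape
Title: Energy-Landscape Analysis of Multi-Network Brain Activity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Fits pairwise maximum-entropy (Ising) models to binarized
    multi-network brain activity time series, constructs the associated
    energy landscape (local minima, basins of attraction, disconnectivity
    tree), quantifies brain-state dynamics empirically and by
    Metropolis-Hastings simulation, and compares groups and behavior
    scores. Includes a synthetic-cohort generator with planted
    ground-truth models so that every stage of the pipeline can be
    validated against known answers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ape,
    withr,
    optparse
Config/testthat/edition: 3
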