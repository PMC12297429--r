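Package: dpcrquant
Title: Digital PCR Quantification, Sensitivity and Cross-Platform Agreement
Version: 0.1.0
Authors@R: person("Analysis", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Poisson-based absolute quantification of gene copy numbers from
    partition-level digital PCR data (nanoplate and droplet platforms), with
    limit-of-detection and limit-of-quantification estimation from dilution
    series, precision and accuracy evaluation against analytically expected
    copy numbers, and cross-platform agreement statistics (Lin's concordance
    correlation coefficient, classic and inverse-variance-weighted
    Bland-Altman analysis). Includes a seeded synthetic-data generator that
    emulates dilution series and cell-count experiments so the whole pipeline
    is testable without instrument exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    Biostrings,
    yaml,
    optparse
Config/testthat/edition: 3
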