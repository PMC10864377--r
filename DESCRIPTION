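Package: nestcr
Title: Closed Capture-Recapture Estimation of Nest Abundance from Repeated
    Drone Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates the number of active nests in colonial-bird breeding
    colonies surveyed by repeated drone flyovers, treating each flyover as a
    capture occasion of a closed-population capture-recapture study. Fits
    the four-model set of closed models (constant or time-dependent
    detection probability, with or without an additive colony effect on the
    logit scale), selects among them by AIC, and reports per-occasion
    detection probabilities and per-colony abundance with lognormal
    confidence intervals on the never-detected fraction. Includes a
    hierarchical synthetic-colony generator in which detection is the
    product of image-assembly, presence, availability, identification and
    interpreter components with cause-labelled non-detections, and a
    simulation-based power analysis for choosing the number of flyovers
    needed to detect a population decline. Reads and writes capture
    histories as CSV and as MARK-style .inp files.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
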