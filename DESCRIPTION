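Package: salivatdm
Title: Salivary Therapeutic Drug Monitoring: Calibration, Validation and
    Adherence Concordance
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational pipeline for a quantitative LC-MS/MS salivary
    therapeutic drug monitoring assay covering 14 antihypertensive drugs and
    two metabolites. Implements the serial-dilution calibration and quality
    control design, weighted through-origin quadratic calibration fitting and
    inverse prediction, the FDA/EMA bioanalytical validation battery
    (accuracy, intra- and inter-day imprecision, recovery, extraction
    efficiency, matrix effect by post-extraction addition, internal-standard
    normalized matrix effect, selectivity, signal-to-noise based limit
    determination), collection-device retention analysis, and multi-matrix
    adherence classification with concordance statistics. A synthetic
    instrument-signal generator with session, replicate and matrix-lot
    variance components makes every stage testable end to end without raw
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    tibble,
    dplyr,
    tidyr,
    readr
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
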