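Package: hesassay
Title: Quantification of Homeostatic Early Shrinkage and Epithelial Cell Extrusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measurement pipeline for homeostatic early shrinkage (HES) and
    live-cell extrusion in epithelial monolayers. Implements the lightning
    assay (junctional phase-brightness thresholding, baseline-normalised
    suprathreshold area tracking and shrink-event calling), cell-volume
    quantification from 3-D reporter stacks and the Calcein quench proxy,
    per-cell fluorescence onset and lag kinetics (DiBAC4(3), CoroNa, ATP
    reporters), quantitative-phase-imaging dry-mass trajectories, and cohort
    event statistics with bootstrap intervals. Ships a synthetic time-lapse
    generator that renders confluent polygonal monolayers with ground-truth
    extrusion, shrinkage, depolarisation and ion-entry events, so that the
    entire pipeline can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
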