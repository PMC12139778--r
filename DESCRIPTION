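Package: simpullr
Title: Single-Molecule Pulldown Photobleaching Stoichiometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of two-channel single-molecule pulldown
    (SiMPull) TIRF experiments for subunit stoichiometry inference by
    photobleaching step counting. Generates ground-truth-annotated synthetic
    movies and intensity traces, detects diffraction-limited spots, registers
    and colocalizes the two channels, extracts and normalizes per-spot
    intensity traces, counts photobleaching steps with a rule-based
    changepoint oracle, trains one-dimensional convolutional neural network
    classifiers under inverse-class-frequency loss weighting, and summarizes
    per-replicate stoichiometry with a nested one-way analysis of variance.
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
    withr
Config/testthat/edition: 3
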