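Package: sarcomech
Title: Sarcomere Morphometry and Muscle Mechanics Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis pipeline for skeletal-muscle structure and
    function studies: segmentation and morphometry of thick myosin filaments in
    cross-sectional electron micrographs (per-filament cross-sectional area and
    six-nearest-neighbour interfilament spacing), skinned single-fiber
    contractile fitting (force redevelopment rate, tension-pCa, isotonic
    shortening velocity, Hill force-velocity and power-load curves),
    whole-muscle force normalization and calcium-transient kinetics,
    spectral detection of high-frequency tremor bursts in force-plate
    recordings, and droplet digital PCR and radiographic quantification
    helpers. A companion synthetic-data module generates every input with
    known ground truth so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    minpack.lm,
    signal,
    stats,
    utils,
    withr
Suggests:
    jsonlite,
    png,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
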