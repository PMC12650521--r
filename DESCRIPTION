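Package: glucopad
Title: Smartphone Colorimetric Glucose Readout for Paper-Based Devices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative colorimetric readout for paper-based (uPAD) glucose
    test chips photographed with a smartphone. Converts chip photographs to
    the 8-bit HSV color space, segments the TMB (3,3',5,5'-tetramethylbenzidine)
    blue-green reaction zone with configurable HSV range thresholds, computes a
    normalized color-intensity score from the binary mask, maps the score to a
    glucose concentration in mg/dL through a linear calibration (built-in
    whole-blood and plasma models or user-fitted), classifies readings into
    clinical bands, and emits machine-readable reports. A deterministic
    synthetic chip-image generator with exact ground truth (geometry, target
    glucose, intended intensity) makes the entire pipeline testable without
    laboratory photographs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    jsonlite,
    png,
    stats,
    grDevices,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
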