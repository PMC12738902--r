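Package: transplantQC
Title: Tracking-by-Detection Counting and Quality Evaluation for Mechanized
    Transplanting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detector-agnostic toolkit for assessing the quality of mechanized
    vegetable transplanting from field video. Associates per-frame seedling
    detections (normal, buried-seedling, bare-root) into identities with a
    Kalman-filter / Hungarian-assignment tracker using appearance
    re-identification galleries and cascade matching, tallies each identity
    once as it crosses a virtual counting line, and evaluates counts against
    manual ground truth with mean counting accuracy, MAE and RMSE. Includes a
    synthetic field-pass simulator for end-to-end testing, detection metrics
    (precision, recall, average precision, F1), and reference implementations
    of a quality-focal classification loss and a triplet-attention forward
    pass.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
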