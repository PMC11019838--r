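Package: peakcascade
Title: Rare-Event Peak Detection and Cascaded Classification for
    Backscatter Flow Cytometry Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for label-free detection of rare circulating tumor cell
    clusters (CTCCs) in multi-channel backscatter flow cytometry voltage
    traces. Implements a two-stage pipeline: anomaly-based region-of-interest
    detection (blood-clot baseline correction, zero-phase Butterworth
    band-pass filtering, per-segment normalization, principal-component
    Hotelling T-squared scoring, shoulder-equalized full-width-at-half-maximum
    morphometry and a multicellular width gate) followed by a cascaded
    ensemble of small one-dimensional convolutional networks trained with a
    combined weighted binary cross-entropy and focal Tversky loss. Includes a
    synthetic trace simulator with known ground truth, confusion-matrix
    performance metrics, false-alarm-rate estimation, Poisson blood-volume
    planning and coefficient-of-variation analysis for rare-event counting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
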