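Package: pulsewave
Title: Continuous Photoplethysmogram Pulse-Wave Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: End-to-end analysis of single-channel photoplethysmogram (PPG)
    recordings: zero-phase band-pass and moving-average preprocessing with
    computation of the first three signal derivatives, adaptive windowed
    systolic-peak detection, pulse-wave segmentation, standardized
    fiducial-point detection and correction on the PPG and its derivatives,
    engineering of 74 morphological pulse-wave biomarkers with per-window
    summary statistics, a template-matching signal-quality index, beat-detector
    evaluation (F1 beat matching, fiducial error statistics, Bland-Altman
    agreement), and a synthetic PPG generator with analytic ground truth for
    validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    e1071,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
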