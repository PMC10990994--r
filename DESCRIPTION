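Package: gazeqc
Title: Data Quality and Area-of-Interest Dwell Analysis for
    Calibration-Free Gaze Estimates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to evaluate webcam and computer-vision gaze estimates
    without calibration: visual-angle geometry for fixation grids,
    grid-session data-quality statistics (scale-ratio accuracy,
    spread-to-separation precision, data loss, blink flagging),
    histogram-based area-of-interest segmentation of horizontal gaze
    angles, hysteresis dwell detection, dwell-based looking measures,
    and absolute-agreement comparison against manual coding via the
    intraclass correlation ICC(A,1).  Includes synthetic-session
    generators with known ground truth for grid fixation recordings and
    infant free-looking sessions, plus end-to-end pipelines for both
    study designs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
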