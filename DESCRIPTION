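Package: orchardtrack
Title: Individual-Fruit Growth Monitoring from Time-Series Orchard Images
Version: 0.1.0
Authors@R:
    person("Orchardtrack", "Developers", email = "orchardtrack@example.org",
           role = c("aut", "cre"))
Description: Tools for monitoring the growth of individual fruits in
    fixed-point orchard image time series. Provides a cut-and-paste
    compositor that synthesizes canopy images with occlusion-inclusive
    (amodal) per-fruit masks for training instance-segmentation models,
    VIA polygon annotation input/output with polygon/mask conversion and
    image tiling, a same-fruit tracking algorithm that matches detections
    across days through distance, size and Hu-moment contour gates with
    non-detect-day relaxation, a logistic growth-curve fitter that
    predicts the fruit radius at harvest in real time, and the standard
    instance-segmentation evaluation metrics (precision, recall, IoU,
    MAPE, correlation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    yaml,
    stats,
    utils,
    grDevices,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
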