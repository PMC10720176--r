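Package: berrytrack
Title: Single-Berry Tracking and Ripening Kinetics from Time-Lapse Bunch Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures and tracks individual grapevine berries on time-lapse
    images of a single bunch. Infers full elliptical berry shapes from
    detection boxes and segmentation masks (pluggable predictors), extracts
    per-berry projected area, sphere-equivalent volume and centred hue,
    assigns time-consistent identities with affine coherent point drift
    registration and a matching-tree label propagation, and derives
    single-berry ripening descriptors (growth resumption time, coloration
    start, ripening duration and relative speed). Ships a ground-truthed
    synthetic time-lapse bunch simulator and the accuracy metrics used to
    evaluate detection, segmentation and tracking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
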