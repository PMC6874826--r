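Package: standcount
Title: Seedling Stand Counting in Field Videos by Tracking-by-Detection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Counts crop seedlings in ground-level video of a crop row without
    counting any plant twice. Per-frame bounding-box detections are linked
    across frames by a constant-velocity Kalman filter over the box state
    (center, area, aspect ratio), with frame-to-frame association solved as a
    minimum-cost assignment on negative intersection-over-union and a lifetime
    filter that discards short-lived spurious tracks. Includes CLAHE value-channel
    frame preprocessing, COCO-style detection metrics (AP, AR100, F1 at single
    and averaged IOU thresholds), regression-based counting-accuracy evaluation,
    and a synthetic moving-camera row-scene generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    clue,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    withr,
    EBImage,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
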