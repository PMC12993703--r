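Package: surgaze
Title: Surgeon Gaze-Point Estimation from Surgical Instrument Geometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Estimates the surgeon's gazing point in open-surgery video
    frames from the geometry of detected surgical instruments. Each
    instrument's long axis is fitted from its segmentation mask by image
    moments; pairwise axis intersections are candidate gaze points;
    aberrant intersections are discarded with the Local Outlier Factor;
    the centroid of the remaining intersections is the per-frame gaze
    estimate, optionally stabilised by windowed time averaging with
    within-window outlier exclusion. Includes readers for Labelme polygon
    annotations, PNG masks and COCO-style detections, a synthetic scene
    generator with known ground-truth gaze for end-to-end validation, and
    evaluation metrics (radial correct-circle accuracy, box IoU, AP50).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    yaml
Suggests:
    png,
    optparse,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
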