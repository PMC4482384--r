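Package: isoscale
Title: Two-Dimensional Scale Calibration of OCT B-Scans Using Spherical
    Fiducial Beads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Optical coherence tomography (OCT) B-scans often carry unequal
    X (lateral) and Y (axial) pixel scales, so circular structures display as
    ellipses and oblique lengths and angles are distorted. isoscale provides
    the closed-form corrections for distances and angles measured in such
    anisotropic images, and estimates the X/Y correction factor k = a/b from
    cross-sections of spherical fiducial beads of known diameter: beads are
    segmented, each cross-section is fitted with an ellipse by direct
    least squares, and per-bead axis ratios are aggregated into a calibration
    (mean +/- SD) with group comparison by Student's t-test. A calibration can
    then be applied to resample the Y axis so that both scales agree, or to
    correct individual measurements on uncorrected scans. A seeded synthetic
    phantom generator with exact ground truth supports validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
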