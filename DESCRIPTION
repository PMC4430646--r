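Package: gait2d
Title: Single-Camera 2D Markerless Gait Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates sagittal-plane lower-limb kinematics (hip, knee and
    ankle flexion-extension, pelvic tilt), gait events and spatiotemporal
    parameters from a single lateral video of a walking subject wearing
    white ankle socks and underwear against a homogeneous blue background.
    A subject-specific multisegmental model (foot, tibia, femur, pelvis) is
    calibrated from a static reference image and operator-identified
    anatomical landmarks; segments are tracked bottom-up by contour
    template matching and SVD rigid registration of silhouette reference
    points, with a double-calibration scheme for the pelvis. Includes a
    ground-truthed synthetic articulated-walker renderer so that the whole
    pipeline can be exercised and validated without recorded video, and the
    agreement statistics (RMSD, MAE, linear-fit shape similarity) used to
    compare kinematic waveforms against a reference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    signal,
    jsonlite,
    yaml,
    png,
    stats,
    utils,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
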