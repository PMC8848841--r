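Package: elbowaxis
Title: Instantaneous Rotation Axis of the Ulnohumeral Joint from 4D-CT Surface Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates the instantaneous rotation axis of the ulnohumeral
    (elbow) joint from posed surface models of the proximal ulna, expresses
    where the axis pierces the medial and lateral aspects of the distal
    humerus in an anatomical landmark coordinate system, and quantifies how
    those intersections migrate with elbow flexion. Includes single-threshold
    segmentation of image volumes to bone surfaces, a parametric synthetic
    elbow generator with known ground-truth kinematics for validation, a
    finite helical axis oracle, trend statistics and the two-group sample
    size computation, and a configuration-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    RNifti,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
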