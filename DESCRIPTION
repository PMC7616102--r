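Package: planepose
Title: Plane Pose Regression and Registration for Fetal Brain Ultrasound Volumes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.com")
Description: Tools for localizing 2D ultrasound imaging planes inside 3D
    fetal-brain volumes. Provides rotation mathematics built on the
    continuous 6D rotation representation (Gram-Schmidt decoding, geodesic
    and quaternion angular distances, chordal L2 rotation averaging and RMS
    pose-spread statistics), a synthetic fetal-brain phantom generator with
    named fiducials and a designated standard-plane pose, arbitrary-pose
    slice extraction with trilinear interpolation and supervised dataset
    generation, closed-form fiducial-based similarity (7 degree-of-freedom)
    registration with fiducial and masked-intensity RMS metrics, a compact
    convolutional pose-regression network with a 9-parameter head trained by
    Adam, and leave-one-out cross-validation drivers with pose-error
    summaries and annotation-variance reports.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    png,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
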