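Package: duotomo
Title: Dual-Modal Photoacoustic and Ultrasound Breast Tomography Simulation and Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates half-ring-array photoacoustic and synthetic-aperture
    pulse-echo ultrasound acquisitions of two-dimensional breast phantoms,
    reconstructs both modalities by weighted delay-and-sum beamforming
    (bipolar and unipolar photoacoustic variants; angle-gated synthetic
    aperture with incoherent compounding for ultrasound), post-processes
    photoacoustic angiograms (adaptive depth compensation, multiscale
    Frangi vesselness, vessel skeletonization, slice registration,
    depth-encoded projections), extracts tumor-zone vascular and
    anatomical features, and fits a small one-dimensional convolutional
    network that outputs a probability of malignancy, with exact
    Clopper-Pearson confusion-matrix statistics, feature selection and
    permutation importance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    grDevices,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
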