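Package: mmri
Title: Marker-Free Measurement of Implant Migration from Low-Field MRI
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Measures rigid-body migration of a joint implant relative to its
    host bone from repeated 3D MRI acquisitions, without implanted markers.
    Provides semi-automatic segmentation (profile-line window thresholding,
    region growing, morphological closing, iso-surface extraction), three
    rigid registration strategies (landmark-guided manual surrogate,
    automatic model-based, and model-free using the first acquisition as
    reference), orthogonal-Procrustes six-degree-of-freedom migration
    computation on anatomical axes, and zero-motion precision statistics
    with comparison against the RSA golden-standard bands. A synthetic
    phantom generator emulates a tibial tray implanted in a porcine tibia
    suspended in gelatin, with metal-artifact signal voids and Rician
    noise, so the full pipeline is exercisable with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    ggplot2,
    stats,
    utils,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
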