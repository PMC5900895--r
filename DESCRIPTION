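Package: fieldshim
Type: Package
Title: Template-Based B0 Field Map Prediction and Spherical Harmonic Shimming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for whole-brain static B0 shimming of brain MRI. Builds a
    field-map template by averaging co-registered brain field maps in a
    standard space, predicts the field of a new subject from a quick
    structural scan by inverse-warping the template, and computes
    spherical-harmonic shim settings by masked linear least squares.
    Includes dual-echo field-map computation with quality-guided 3D phase
    unwrapping, baseline-shim removal, shim-coil calibration, affine
    registration and resampling utilities, a synthetic cohort generator
    based on Fourier-domain dipole-kernel susceptibility simulation, and a
    leave-one-out cross-validation harness comparing shimming strategies
    (measured, registered, fixed, random and tune-up shims) with paired
    nonparametric testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
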