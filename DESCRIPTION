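Package: atriasim
Title: Desk-Scale Simulation of Human Atrial Electrophysiology and Electrograms
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates human atrial electrical activity at desk scale: the
    Nygren human atrial action-potential model with regional ionic-conductance
    variants and chronic atrial-fibrillation electrical remodeling, an
    anisotropic monodomain reaction-diffusion solver with Strang operator
    splitting on synthetic cable, sheet and ring geometries, pseudo-unipolar
    electrogram computation under the large-volume-conductor approximation,
    and the standard electrogram analysis chain (40-250 Hz band-pass,
    rectification, 20 Hz low-pass, dominant frequency, organization index,
    cycle-length extraction, and single/double/CFAE morphology
    classification), together with scenario drivers for conduction-velocity
    calibration, ring macroreentry, block-line tachycardia and focal
    fibrillation analogues.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    signal,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
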