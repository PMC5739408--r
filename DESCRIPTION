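Package: mbscatter
Title: Moving-Blocker Scatter Correction for Cone-Beam CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", role = c("aut", "cre"),
           email = "author@example.org")
Description: Simulation and correction of X-ray scatter in cone-beam
    computed tomography (CBCT) acquired with a moving beam-blocker: a
    voxel-phantom acquisition simulator with a Siddon ray-traced
    projector, robust multi-view blocker-edge detection (minimum
    envelope plus adaptive thresholding), single-view and multi-view
    cubic B-spline scatter estimation from blocked detector regions,
    total-variation constrained algebraic reconstruction (ART) of the
    attenuation volume from the partially blocked projections, and
    quantitative evaluation in Hounsfield units.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    splines,
    stats,
    graphics,
    jsonlite,
    tiff,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
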