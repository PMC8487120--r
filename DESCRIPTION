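Package: arcview
Title: Optimal C-Arm Viewing-Angle Planning for Thoracic Endovascular
    Aortic Repair
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Determines the optimal angiographic viewing angle for thoracic
    endovascular aortic repair (TEVAR) from a labeled 3D aorta volume and its
    centerline. Simulates parallel-beam angiographic silhouettes across a
    0-90 degree C-arm sweep, computes the projection overlapping rate of the
    left common carotid and left subclavian arteries and the projection
    foreshortening rate of the aortic-arch centerline at every angle, and
    selects the viewing angle either by joint minimization or by an adaptive
    two-step rule that first eliminates branch overlap and then bounds the
    residual foreshortening. Includes a parametric aortic-arch phantom
    generator with analytically known geometry, and the cohort-level
    statistical comparison machinery (normality-gated t / Mann-Whitney tests
    and angle-difference binning).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    RNifti,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    png
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
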