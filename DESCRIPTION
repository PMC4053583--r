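Package: apitv
Title: Adaptive Prior Image Total Variation Reconstruction for Few-View CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Iterative image reconstruction for few-view computed tomography.
    Implements the adaptive prior image total variation (API-TV) algorithm,
    which interleaves algebraic reconstruction (ART/Kaczmarz) data-consistency
    sweeps and positivity projection with gradient descent on a blend of the
    image total variation and the total variation of the difference from a
    prior image reconstructed from a dense-view scan. Includes the ASD-POCS
    and plain ART baselines, a matched Siddon ray-driven forward/back
    projector pair for circular fan-beam geometry, flat-detector fan-beam
    filtered backprojection, analytic Shepp-Logan phantom generation, a white
    noise model for projections, quantitative image-error metrics, and
    scripted simulation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    methods,
    stats,
    utils,
    tiff,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
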