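Package: lithomorph
Title: Three-Dimensional Outline Morphometrics of Convergent Stone Tools
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Geometric-morphometric analysis of closed three-dimensional
    outlines digitized on pointed (convergent) stone tools. Implements
    equal-arc-length resampling of digitized contours into pseudo-landmarks,
    generalized Procrustes superimposition computed on three anchor landmarks
    with propagation of each normalization to the full outline, tangent-space
    projection, three-dimensional elliptic Fourier analysis with harmonic
    power accounting and inverse-Fourier shape reconstruction, principal
    component shape spaces, Pillai-trace MANOVA and discriminant tests of
    shape against use-wear factors, and centroid-size/volume allometry tests.
    A synthetic assemblage generator produces triangular tool-like outlines
    with known shape parameters, factor structure and volumes so that every
    pipeline stage can be validated without access to museum data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    readxl
Config/testthat/edition: 3
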