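Package: growrod
Title: Growth-Driven Movement of Rod-Like Organs in 3D
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the growth-driven movements of slender rod-like organs
    such as plant shoots and roots: tropic bending toward external stimuli
    (distant, point and line sources), inherent circumnutation driven by an
    internal oscillator, and proprioceptive posture control. The organ
    centerline is discretized in a natural (Bishop) frame so that curvature
    dynamics remain well-defined on straight segments; differential growth
    advances the two cross-sectional curvature components through an explicit
    upwind scheme with material advection through a sub-apical growth zone and
    tip segment addition. Includes a planar curvature-dynamics integrator used
    as an independent validation oracle, characteristic length and time scale
    diagnostics (balance number, convergence length and times), and a 2D
    optimal-control formulation of apical tip steering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
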