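Package: oamtwist
Title: Orbital Angular Momentum Twist Refractometry and Phase Memory in Turbid Media
Version: 0.1.0
Authors@R: person("OAM", "Twist Maintainers", email = "oamtwist@example.org", role = c("aut", "cre"))
Description: Forward models and measurement algorithms for probing media with
    orbital-angular-momentum (OAM) light. Evaluates Laguerre-Gaussian (LG) beam
    fields and phases, spiral photon trajectories and their refraction through
    layered media, and converts pathlength increments into phase retardation to
    predict the twist of the petal interference pattern under refractive-index
    change. Includes a Henyey-Greenstein Monte Carlo photon transport with
    semi-analytic detection for turbid tissue-like phantoms, on-axis and
    off-axis interferogram synthesis with a camera model, petal-twist
    quantification (Otsu thresholding, Moore-Neighbor boundary tracing,
    centroid polar angles), off-axis holographic phase retrieval by FFT
    sideband selection, and a phase-memory index mapping retrieved speckle
    phase against applied spatial-light-modulator phase offsets. Synthetic data
    generators emulate thermal refractive-index drift runs and partially
    phase-preserving speckle so the whole chain is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
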