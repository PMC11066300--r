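Package: sptpalm
Title: Single-Particle Tracking PALM Analysis Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A scriptable analysis pipeline for single-particle tracking
    photoactivated localization microscopy (sptPALM) of membrane proteins:
    maximum-likelihood localization of single emitters with an integrated
    Gaussian PSF model and optional sCMOS per-pixel noise handling,
    globally optimal linear-assignment trajectory building with gap
    closing, mean-square-displacement mobility analysis with log10(D)
    population decomposition, and nanoscale cluster analysis (Voronoi
    tessellation, DBSCAN, NASTIC). Includes a synthetic-movie simulator
    with Brownian motion, photoactivation/blinking/bleaching photophysics
    and an sCMOS camera model, plus batch processing with full parameter
    provenance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
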