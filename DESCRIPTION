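Package: sptmsd
Title: Single-Particle Tracking and Mean-Square Displacement Analysis of
    Membrane Protein Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for quantifying the lateral mobility of
    membrane proteins imaged by total internal reflection fluorescence
    (TIRF) microscopy: Laplacian-of-Gaussian spot detection with subpixel
    refinement, linear-assignment-problem (LAP) track linking with gap
    closing, time-averaged and ensemble mean-square displacement (MSD)
    curves, log-log power-law fitting of the generalized diffusion
    coefficient D and anomalous exponent alpha, motion classification
    (anomalous/confined, Brownian, directed), confinement-radius
    estimation, and nonparametric group comparison.  Includes a
    synthetic-data generator (Brownian, fractional Brownian, confined and
    directed trajectories rendered into noisy TIRF-like movies) so the
    whole pipeline is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    minpack.lm,
    tiff,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
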