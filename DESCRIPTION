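Package: loomglide
Title: Looming-Stimulus Geometry and Locust Escape-Response Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying how flying locusts detect and evade looming
    aerial predators. Implements the angular geometry of looming discs (with
    optional wing-like extensions), predator attack-speed estimation from
    digitized video tracks with hierarchical (segment to attack to individual)
    averaging, closing-speed and l/|v| ratio calculations for predator-prey
    convergence, windowed spike-rate analysis of looming-detector (DCMD)
    responses, glide detection from wingbeat sensor event trains, and a
    synthetic-data generator (eta-model inhomogeneous Poisson spike trains,
    jittered wingbeat rhythms with rate-gated glide injection, and noisy pixel
    tracks) so that every pipeline stage can be tested end to end without
    recorded data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
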