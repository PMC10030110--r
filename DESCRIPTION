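Package: runeven
Title: Biomechanics of Running on Undulating Uneven Terrain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for studying how runners regulate footsteps and
    fore-aft collision impulses on undulating uneven terrain. Provides gridded
    terrain height fields and their roughness statistics, calibrated synthetic
    data generators (terrain, marker trajectories, force-plate traces,
    respirometry) with known ground truth, gait-event detection and per-step
    kinematics, zero-phase force filtering and normalized fore-aft impulse
    computation, blind and terrain-directed (Markov chain) foot-placement
    models with a foot-placement index, a planar four-link rigid/compliant
    collision model of heel strike, and net metabolic rate estimation from
    breath-by-breath respirometry.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
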