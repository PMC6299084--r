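Package: flamech
Title: Mechanics of Two-Flagellin Bacterial Flagella and 3D Swimming Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates the mechanics of bacterial flagellar filaments built
    from two flagellins (FlaA/FlaB) with distinct equilibrium helix
    geometries, using a discrete elastic rod (bead-spring) model with
    resistive-force-theory hydrodynamics, motor torque driving, polymorphic
    state switching and adaptive embedded Runge-Kutta (Cash-Karp) time
    integration. Provides a screw-formation analysis pipeline (torque
    thresholds, composition-torque stability diagrams, force-torque
    efficiency), digital inline holography utilities (median background
    removal, Rayleigh-Sommerfeld/angular-spectrum back-propagation, 3D
    localization, track linking), run-tumble trajectory statistics (spline
    smoothing, motility classification, reorientation detection, run/speed/
    turning-angle distributions), and synthetic-data generators for
    closed-loop validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    graphics,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
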