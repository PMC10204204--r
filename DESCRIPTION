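Package: setasim
Title: Agent-Based Model of Suspension-Feeding Setae and Particle Capture
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Numerical model of crustacean suspension feeding: mirrored rows
    of driven bead-spring elastic setae with per-segment stiffness and
    adhesion profiles sweep food particles toward a mouth region. Particles
    couple to the moving filaments and to a uniform external flow through a
    velocity-equilibrating viscous surrogate and adhere to filament tips via
    a Morse potential. Provides the force laws, a deterministic seeded
    time-stepper, named scenario presets, parameter sweeps, consumption and
    avalanche statistics, spatial density maps, and file export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    rlang,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE, load = "installed")
RoxygenNote: 7.3.3
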