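Package: rsmpso
Title: Response Surface Models with Particle Swarm Optimisation for
    Sensory Formulation Studies
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for two-factor food-formulation optimisation studies that
    combine response surface methodology (RSM) with particle swarm
    optimisation (PSO).  Builds central composite designs with explicit
    coded-to-natural level maps, fits full second-order polynomial response
    surfaces to sensory panel means with ANOVA, lack-of-fit and pure-error
    decomposition, and maximises fitted surfaces either analytically
    (stationary point), by exhaustive grid search, or with a global-best
    particle swarm using a linearly decaying inertia weight and a multi-run
    harness.  Ships a registry of published second-order sensory models for
    three heritage bulgur pilaf formulations (Siyez, Firik, Karakilcik),
    closed-form quality metrics (DPPH percent inhibition; CIELAB chroma, hue
    angle and delta-E), and a synthetic hedonic-panel generator for
    parameter-recovery simulation studies.
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
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
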