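Package: lampswim
Title: Neuro-Musculo-Mechanical Simulation of Lamprey Swimming
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates anguilliform swimming of a lamprey as a planar,
    inextensible, viscoelastic multilink rod driven by Hill-type swimming
    muscle with calcium-kinetics activation and work-dependent deactivation,
    a central-pattern-generator travelling wave of square-wave stimulation,
    and Taylor resistive fluid forces. Provides kinematic analysis of the
    resulting trajectories (forward speed, tail-beat amplitude,
    curvature-wave speed and the activation/curvature wave-speed ratio,
    per-segment muscle work), parameter sweeps over tail-beat frequency and
    muscle activation strength with quadratic extraction of speed-maximizing
    combinations, and a closed-loop controller mapping desired swimming
    speed to frequency and activation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    minpack.lm,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
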