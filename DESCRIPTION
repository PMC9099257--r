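Package: grestreus
Title: Two-Dimensional gREST/REUS Replica Exchange on Coarse-Grained Binding Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator for two-dimensional replica-exchange
    molecular dynamics combining generalized replica exchange with solute
    tempering (gREST) and replica-exchange umbrella sampling (REUS), exercised
    on synthetic bead-model protein-ligand binding systems. Provides the full
    practical protocol for setting up such simulations: multi-anchor
    center-of-mass distance collective variables, dual-direction umbrella
    pulling for initial structures, automatic solute-temperature ladder tuning
    toward a target acceptance ratio, umbrella window and force-constant
    tuning from trial-run coverage, an alternating two-dimensional Metropolis
    exchange scheduler over a Langevin (BAOAB) integrator, and the complete
    set of sampling-efficiency diagnostics (acceptance profiles, visitation
    populations, round trips, window-overlap reports, bound-pose hit ratios).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
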