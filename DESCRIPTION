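Package: gelperm
Title: Coarse-Grained Simulation of Nanoparticle Diffusion in Cross-Linked Polymer Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bead-spring molecular dynamics of rigidity-tunable nanoparticles
    diffusing through a regular cross-linked polymer hydrogel network, in reduced
    Lennard-Jones units. Nanoparticles are one-particle-thick deformable shells of
    orientable beads interacting through a distance- and orientation-dependent
    soft-core potential; rigidity is tuned through the shell bead-bead interaction
    strength. Includes a Velocity-Verlet integrator with a Langevin thermostat,
    rigid-body propagation for control ellipsoids, trajectory observables
    (ensemble mean-squared displacement, fitted diffusivity, polymer contact
    counts, gyration-tensor shape metrics), and a two-dimensional multi-particle
    tracking pipeline with a synthetic track generator for effective-diffusivity
    distributions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    withr
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
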