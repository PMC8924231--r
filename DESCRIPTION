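Package: agedrop
Title: Coarse-Grained Simulation of Biomolecular Condensate Ageing
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Sticker-spacer coarse-grained Langevin dynamics of phase-separating
    proteins, built to study how strengthening of inter-protein interactions
    drives condensate maturation. Provides a periodic-box bead-spring engine
    (Lennard-Jones or Wang-Frenkel nonbonded interactions, harmonic bonds,
    cell-list neighbor search, counter-based reproducible noise), builders for
    dilute gases, bulk condensed phases, preformed droplets and tangent droplet
    pairs, and trajectory analysis: windowed mean-square-displacement diffusion
    coefficients, liquid/ageing regime classification, strong-contact counting
    and clustering, condensate density profiles, gyration-tensor shape metrics,
    droplet coalescence times and the kinetic border between coalescence and
    maturation. Turnkey protocol drivers reproduce diffusion scans, nucleation
    and growth, thermal hysteresis, in-droplet maturation and coalescence
    matrices at configurable (desk-scale by default) system sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
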