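Package: egressr
Title: Coarse-Grained Ligand-Egress Sampling, Channel Statistics, and
    Permeability from Potentials of Mean Force
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for studying how an elongated ligand (a quinol-like
    bead chain with an aromatic head ring and an isoprenoid-like tail)
    escapes from a binding site enclosed by a ring of protein-like
    subunits embedded in a membrane slab.  Provides a Langevin dynamics
    engine for coarse-grained toy systems, a self-referenced random
    acceleration molecular dynamics controller (S-RaMD-MD) that drives
    head-first or tail-first egress under membrane-boundary restraints,
    campaign planning and per-channel dissociation statistics, umbrella
    sampling over an xy-projected reaction coordinate with a WHAM solver
    and convergence diagnostics, permeability coefficients from the
    inhomogeneous solubility-diffusion model, and geometric detectors for
    hydrogen bonds, pi-stacking and water bridges on labelled coordinate
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    stats,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
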