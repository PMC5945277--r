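Package: bendrc
Title: Conformational Ensemble Analysis of Protein Bending Motions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing conformational ensembles of flexible
    proteins such as the tubulin dimer: Kabsch superposition and principal
    component analysis of structure ensembles, a randomized search for the
    linear reaction coordinate that best separates two ensembles by
    minimizing the overlap of their projected densities, partial
    least-squares functional mode analysis of a scalar functional quantity
    (e.g. RMSD to a straight reference structure), and free-energy
    reconstruction from umbrella-sampling windows by WHAM with Bayesian
    bootstrap and block-average error estimates, including basin depths,
    free-energy differences and two-state Boltzmann populations. A
    synthetic-data module generates ensembles, hinge-dimer bead models and
    umbrella windows with analytically known ground truth so that every
    stage of the pipeline can be validated without molecular-dynamics
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
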