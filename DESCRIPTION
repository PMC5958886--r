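Package: sshelix
Title: Helix Unfolding Kinetics from Secondary-Structure Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis of alpha-helix unfolding in molecular-dynamics
    trajectories through per-residue secondary-structure labels (the
    eight-class DSSP alphabet). Provides readers and writers for label
    trajectories, unfolding-time detection, region-ordered unfolding
    classification, residue-resolved transition-probability estimation
    over one snapshot lag, helix-end (triad) elongation and unwinding
    propensities, coordinate-based chain metrics (end-to-end distance,
    radius of gyration), and a kinetic Zimm-Bragg Monte-Carlo generator
    of synthetic label trajectories for validation and parameter
    recovery without running molecular dynamics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    ggplot2,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
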