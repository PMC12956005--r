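Package: dimerstab
Title: Interface Hydrogen Bonding and Elastic-Network Stability Analysis of
    Homodimer Point Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Structural analysis of point variants at protein homodimer
    interfaces, motivated by gain-of-function variants of Toll-like receptor 8.
    Provides fixed-column PDB parsing and writing (including multi-model files
    treated as trajectories), deterministic ideal-geometry side-chain
    mutagenesis with polar-hydrogen placement, geometric hydrogen-bond and
    water-mediated interchain bridge detection under configurable
    distance/angle cutoffs, anisotropic elastic-network normal-mode analysis
    with a vibrational-entropy and contact-based stability proxy, per-frame
    water-bridge statistics over trajectories with block-bootstrap
    comparisons, and self-checking synthetic fixture generators for testing
    every stage without external structure downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'config.R'
    'dimerstab-package.R'
    'structure-utils.R'
    'enm.R'
    'topology.R'
    'hydrogens.R'
    'hbonds.R'
    'mutate.R'
    'pdb-io.R'
    'trajectory.R'
    'stability.R'
    'pipeline.R'
    'synthetic.R'
    'utils-geometry.R'
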