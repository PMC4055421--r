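Package: psnet
Title: Ensemble Analysis of Protein Structure Networks and Allosteric Communication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistical-ensemble analysis of protein structure networks from
    conformational ensembles (multi-model PDB). Computes residue force-constant
    rigidity profiles from inter-residue distance fluctuations, B-factors,
    residue-depth solvent-protection profiles, dynamic cross-correlation
    matrices and principal modes, side-chain interaction networks with
    interaction-strength normalization and ensemble occupancy filtering,
    k-clique percolation communities, and correlation-weighted centrality and
    suboptimal-path analysis of allosteric communication. Includes a synthetic
    ensemble generator (Gaussian-network, rigid two-domain hinge, planted
    community graphs) with analytic oracles for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    MASS,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
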