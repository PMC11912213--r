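Package: ktnkit
Title: Kinetic Transition Network Analysis of Peptide Energy Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing kinetic transition networks (KTNs) of
    peptide energy landscapes: readers for PATHSAMPLE-style stationary-point
    databases, harmonic transition-state-theory rate matrices, master-equation
    first-passage-time distributions by eigendecomposition, graph
    transformation network reduction, threshold funnel clustering and
    disconnectivity graphs, ensemble structural descriptors (RMSD, RMSF,
    radius of gyration, contact maps, solvent-accessible surface area),
    Boltzmann-weighted hydration free energies, and a graph convolutional
    solubility scorer with additive per-residue attribution. Includes
    synthetic generators for multi-funnel landscapes, toy peptide ensembles
    and labelled solubility graph datasets with planted ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    bio3d,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
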