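Package: reanet
Title: Graph-Theoretical Reaction Network Analysis of Molecular Trajectory Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyzes ensembles of molecular geometry snapshots (multi-frame XYZ
    trajectories with per-frame energies, e.g. from metadynamics conformer
    exploration) for reactive events. Molecular graphs are perceived from
    Cartesian coordinates with distance criteria for covalent, organometallic,
    hydrogen-bond and ionic interactions; unique chemical species are
    identified by canonical labeled-graph fingerprints; a directed reaction
    network of species and transformation energies is assembled, trimmed under
    user-defined node and edge energy thresholds, and styled for visualization.
    Connected-component (breadth-first search) fragment analysis extracts
    unique transition-metal (pivot) fragments from multi-metal systems. A
    synthetic trajectory generator with programmed reaction events supports
    fully self-contained validation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
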