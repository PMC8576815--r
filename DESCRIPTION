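Package: alloSPM
Title: Shortest Path Maps and Conformational Ensemble Analysis for
    Allosteric Enzyme Design
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for identifying conformationally relevant residues in
    enzymes from conformational ensembles and turning them into small,
    testable mutation sets. Computes dynamical cross-correlation matrices
    (DCCM) from superposed multi-model PDB or XYZ ensembles, builds residue
    contact networks weighted by -ln|C_ij|, extracts shortest path maps
    (SPM) ranking residues by their participation in inter-residue
    communication pathways, and filters SPM positions against a stand-alone
    template sequence with multiple-sequence-alignment conservation banding
    to propose candidate mutations. Also projects ensembles onto ordered
    open-to-closed reference paths via path collective variables (s, z),
    builds weighted free-energy surfaces, and scores closed-state retention.
    Includes seeded synthetic generators (correlated ensembles with planted
    contact paths, template/target sequence pairs, alignments with planted
    conservation) so the whole workflow is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    bio3d,
    Biostrings,
    igraph,
    Matrix,
    MASS,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
biocViews: StructuralPrediction, Network, Alignment, Software
RoxygenNote: 7.3.3
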