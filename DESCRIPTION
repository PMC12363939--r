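Package: structforge
Title: Atom-Level Structure Sanitization, Featurization and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A modular toolkit for preparing biomolecular structures for
    machine-learning and modelling workflows. Reads mmCIF/PDB structures and
    CCD-style chemical component dictionaries into a shared atom-level table,
    applies composable sanitization transforms (altloc resolution, leaving-group
    removal, covalent-link detection, bond-order correction, formal-charge
    assignment, symmetry-ligand deduplication, coordinate imputation), derives
    chirality and pairwise-distance conditioning features, generates reference
    conformers by empirical force-field minimization, builds extended backbones
    for disordered regions, and scores structures with lDDT, interface lDDT,
    backbone RMSD and relative solvent accessibility under a clustered-mean
    evaluation protocol.
License: MIT
Encoding: UTF-8
SystemRequirements: Python (>= 3.8) with the rdkit package, used by the
    bundled conformer-embedding helper.
Depends: R (>= 4.2)
Imports:
    bio3d,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
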