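Package: rinens
Title: Residue Interaction Networks for Structural Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Geometric-rule detection of typed non-covalent residue-residue
    interactions (hydrogen bonds, ionic bonds, pi-pi stacks, pi-cation,
    van der Waals contacts, disulphides) in single- and multi-state protein
    and nucleic-acid structures, and ensemble-level analyses built on the
    resulting residue interaction networks: interaction frequencies,
    probabilistic contact maps, contact-count correlations across states,
    and RMSD-based hierarchical clustering with medoid representatives.
    Reads multi-model PDB and mmCIF files; includes deterministic synthetic
    structure generators used throughout the test suite.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
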