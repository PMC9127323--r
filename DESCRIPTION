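Package: anchormod
Title: Anchor-Restrained Homology Modelling of Peptide-MHC Class I Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds three-dimensional models of peptide-MHC class I (pMHC-I)
    complexes by anchor-restrained homology modelling. Curates a template
    database from PDB structures (chain extraction, renumbering, tolerated
    non-canonical residue substitution, groove-ligand filtering), selects
    templates through an allele hierarchy (allele, group, gene) with an
    anchor-position-driven peptide alignment ranked by PAM30, grafts the
    target onto the template, and generates ranked peptide loop models by
    seeded randomization followed by two-phase restrained energy
    minimization. Includes a full evaluation stack (G-domain superposition,
    ligand RMSD in several atom dialects, CAPRI quality classes, hit-rate
    and success-rate curves), a deterministic synthetic pMHC fixture
    generator, emission of MODELLER-compatible PIR inputs, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
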