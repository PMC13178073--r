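Package: bindmode
Title: Binding-Mode Energetics and Pharmacology of Nuclear-Receptor Ligands
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-point binding free-energy analysis for receptor-ligand
    snapshot ensembles: single-trajectory MM-GBSA with generalized Born
    (OBC, igb=2-style) implicit solvation, an interaction-entropy term,
    per-residue energy decomposition, and pose-hypothesis ranking; plus
    trajectory stability metrics (RMSD, RMSF, SASA), circular Morgan
    fingerprints with Tanimoto similarity, and TR-FRET dose-response
    pharmacology (four-parameter logistic fits, Cheng-Prusoff inhibition
    constants, efficacy normalization and ligand-profile classification).
    Synthetic generators provide host-guest ensembles, interaction-energy
    streams and dose-response plates with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
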