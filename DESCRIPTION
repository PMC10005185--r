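Package: agscreen
Title: Structure-Guided Screening Descriptors and Pocket Analysis for ABA
    Receptor Agonists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-docking analysis toolkit for structure-guided discovery of
    abscisic acid (ABA) receptor agonists and receptor engineering.
    Implements physicochemical library filtering (molecular weight and
    hydrogen-bond donor/acceptor counts), pharmacophore sphere-occupancy
    scoring of docked ligand poses, rank aggregation of docking scores with
    descriptor occupancies, binding-pocket definition and residue diffing
    between superposed homologous receptors, geometric detection of
    hydrogen bonds, water bridges, the Trp-lock motif and hydrophobic
    tunnel contacts, and ligand torsion-strain reporting against reference
    torsion statistics.  Ships seeded synthetic-structure generators so the
    whole pipeline is testable without external structure downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    yaml,
    jsonlite,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
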