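Package: xlcomplex
Title: Crosslinking-MS Restraint Simulation and Complex Model Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for the non-neural computational steps of
    crosslinking-mass-spectrometry assisted protein complex modelling:
    chemistry-aware simulation of crosslink restraints from structures
    (tryptic digestion, Shrake-Rupley solvent accessibility, reactive-residue
    chemistry, distance cutoffs) with FDR-controlled decoy injection and
    link-level FDR annotation; encoding of crosslink sets as soft-label
    contact-map restraints; DockQ interface-quality scoring (Fnat, interface
    RMSD, ligand RMSD, CAPRI classes); crosslink satisfaction and noise
    rejection scoring of candidate models; and confidence-first or
    crosslink-first model ranking. Includes a deterministic synthetic-fixture
    generator (ideal helices, two-chain complexes, decoy ladders) and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
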