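Package: betacatch
Title: Detection of Beta-Strand Degrons in Catch-Domain Complexes and
    GPS Stability-Screen Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies substrate beta strands captured between the two
    anchor strands of the midnolin Catch domain in predicted two-chain
    complex structures. Reads PDB models (per-residue pLDDT in the
    B-factor column), assigns extended secondary structure with an
    internal Kabsch-Sander hydrogen-bond algorithm, detects captured
    strands from C-alpha distance matrices with a 5.5 Angstrom
    double-anchor rule, annotates inward/outward side-chain facing by
    the C-beta/C-alpha parity rule, and computes cohort statistics
    (positional amino-acid enrichment, hydrophobicity and pLDDT
    disorder contrasts via paired t-tests). Also computes the protein
    stability index (PSI) and its change (delta PSI) from six-bin GPS
    reporter-screen read counts, and ships seed-deterministic
    generators for idealized beta-sheet capture complexes, decoys, and
    simulated screen count tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    stats,
    utils,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
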