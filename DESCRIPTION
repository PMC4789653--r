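Package: glycanfold
Title: Conformational Analysis of Biantennary N-Glycans in 3D Structures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the biantennary N-glycan motif (with or without bisecting
    GlcNAc) in PDB and mmCIF structures, computes glycosidic torsion angles
    (phi/psi/omega) with carbohydrate-standard atom definitions, classifies the
    global conformation of the Manalpha1-6Man arm against five reference
    conformers (half-back-fold, tight-back-fold, back-fold, extend-a,
    extend-b), and runs geometric checks used to reason about glycan
    conformation: proton-proton NOE distance compatibility, intramolecular
    hydrogen bonds, van der Waals clashes, and Kabsch fragment superposition
    for model extension. Includes an internal-coordinate glycan builder that
    generates synthetic biantennary glycan coordinates at prescribed torsions
    for testing and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
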