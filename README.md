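# glycanfold

Conformational analysis of biantennary N-glycans in macromolecular
structures.

Complex-type biantennary N-glycans are flexible: the Manα1–6Man arm swings
between folded and extended states, and attaching a *bisecting GlcNAc*
(β1–4 on the core mannose, residue GlcNAc-7) restricts that freedom. Lectins
such as Calsepa and PHA-E select a *back-fold* conformer, in which the α1–6
arm flips back towards the chitobiose stem. `glycanfold` provides the
computational side of this kind of study for structural glycobiologists:

* **Motif detection** — finds the branching unit
  GlcNAcβ1–2Manα1–3[GlcNAcβ1–2Manα1–6]Man (± bisecting GlcNAc, ± chitobiose,
  ± terminal Gal / core Fuc) in PDB or mmCIF files, inferring glycosidic
  connectivity from geometry alone.
* **Torsion analysis** — glycosidic dihedrals with the carbohydrate-standard
  atom quadruples: φ = O5–C1–O–Cx′, ψ = C1–O–Cx′–C(x−1)′ and, for 1–6
  linkages, ω = O–C6′–C5′–C4′; ω rotamers binned as *gg* (60°), *gt* (180°),
  *tg* (−60°).
* **Conformer classification** — the (φ, ψ, ω) triple of the Manα1–6Man
  linkage is assigned to the nearest of five reference conformers
  (half-back-fold, tight-back-fold, back-fold, extend-a, extend-b) by
  Euclidean distance on wrapped angular differences, with a 45° cutoff:
  label = argmin over refs of √(Δφ² + Δψ² + Δω²), each Δ wrapped into
  (−180°, 180°].
* **Geometric checks** — reconstructed ring/amide hydrogens, NOE-reporter
  proton distances (Man-3 H1 ↔ GlcNAc-5′ H1, Man-3 H1 ↔ Man-4′ H2),
  hydrogen-bond and van der Waals clash detection, Kabsch superposition and
  fragment grafting for model extension.
* **Synthetic builder** — ideal-geometry biantennary glycans at any
  prescribed torsions, emitted as PDB/mmCIF, so the whole pipeline is
  testable without downloads; survey statistics (circular means ± spread,
  class counts, histograms) over a dataset manifest.

## Worked example

Build a bisected glycan in the back-fold conformation, rescan the emitted
file and inspect its torsions, class and reporter proton distances:

```r
library(glycanfold)

f <- file.path(tempdir(), "backfold_bisected.pdb")
cmd_build(preset = "back-fold", out = f)
res <- scan_structure(f)[[1]]

res$torsions[, c("linkage_label", "phi", "psi", "omega")]
#>        linkage_label        phi        psi    omega
#> 1  GlcNAc(b1-2)Man-4 -106.96243  -93.01485       NA
#> 2 GlcNAc(b1-2)Man-4' -107.02907  -93.04302       NA
#> 3       Man(a1-3)Man   81.98911 -128.96859       NA
#> 4       Man(a1-6)Man   69.97291   90.01352 60.03983
#> 5    GlcNAc(b1-4)Man  -75.97936  106.95222       NA

res$assignment
#> back-fold (distance 0.05 deg to back-fold; runner-up half-back-fold at 30.01)

proton_distances(res$motif)
#>                    pair distance noe_compatible
#> 1 man3 H1 - glcnac5p H1 4.102321           TRUE
#> 2    man3 H1 - man4p H2 4.981705           TRUE
```

The five rows are the five glycosidic linkages of the core motif; the file
round trip recovers the requested torsions to the coordinate precision of
the PDB format (≈0.05°). The Manα1–6Man triple (70, 90, 60) classifies as
back-fold, and in this folded arrangement both NOE-reporter proton pairs
fall under the 5 Å observability threshold — the geometric signature that
distinguishes back-fold from extended conformers, where the same distances
are 7–9 Å.

Classifying a measured lectin-bound triple directly:

```r
classify_conformer(c(95, 105, 58))
#> back-fold (distance 29.22 deg to back-fold; runner-up half-back-fold at 51.52)
```

A thin command-line front end is installed at
`system.file("scripts", "glycanfold", package = "glycanfold")` with
`scan`, `build` and `geometry` subcommands.

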