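---
title: "Methods: glycan conformer analysis in glycanfold"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: glycan conformer analysis in glycanfold}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycanfold)
```

## The problem and the model

A complex-type biantennary N-glycan is a small branched tree:
GlcNAcβ1–2Manα1–3[GlcNAcβ1–2Manα1–6]Man on top of a chitobiose stem, with
an optional bisecting GlcNAc attached β1–4 to the core mannose. Pyranose
rings are conformationally rigid on the relevant scale (the ⁴C₁ chair for
the D-sugars here), so the shape of the whole glycan is, to a good
approximation, the vector of glycosidic torsions. `glycanfold` treats a
glycan exactly that way: rigid residues, flexible linkages.

Torsions use the carbohydrate-standard atom quadruples, with unprimed atoms
on the donor (the residue giving its anomeric C1) and primed atoms on the
acceptor:

| linkage | φ | ψ | ω |
|---|---|---|---|
| Manα1–3Man | O5–C1–O–C3′ | C1–O–C3′–C2′ | — |
| Manα1–6Man | O5–C1–O–C6′ | C1–O–C6′–C5′ | O–C6′–C5′–C4′ |
| GlcNAcβ1–4Man | O5–C1–O–C4′ | C1–O–C4′–C3′ | — |
| GlcNAcβ1–2Man | O5–C1–O–C2′ | C1–O–C2′–C1′ | — |

Angles live in (−180°, 180°]; report layers may display 0–360° but the data
model never does. The IUPAC sign convention is used (clockwise positive
looking from the second to the third atom; cis = 0, trans = 180). ω is
measured against C4′, which puts the staggered rotamers *gg*, *gt*, *tg* at
60°, 180° and −60° (equivalently 300°).

The *global* conformation of the glycan is summarised by the Manα1–6Man
triple (φ, ψ, ω) and assigned to the nearest of five reference conformers
from replica-exchange MD — half-back-fold (70, 60, 60), tight-back-fold
(70, 60, 180), back-fold (70, 90, 60), extend-a (70, 180, 60) and extend-b
(70, 180, 180) — within a Euclidean distance of 45°.

Two numerical points are worth making explicit:

* **The metric is toroidal.** Angular differences are wrapped into
  (−180°, 180°] before the Euclidean norm. Without wrapping, a triple with
  ω = −179° would be 359° away from a reference at ω = 180° and extend-b
  conformers near the seam would be misclassified.
* **Nearest reference, not ball membership.** The half-back-fold and
  back-fold references are only 30° apart, so their 45° balls overlap.
  Assignment is argmin over references; "unclassified" means the nearest
  reference is farther than the cutoff. Exact ties (measure-zero, e.g. the
  point (70, 75, 60)) resolve to the reference listed first, in the fixed
  order half-back-fold, tight-back-fold, back-fold, extend-a, extend-b —
  a determinism rule, not a scientific claim.

Dataset statistics are circular: the mean direction is atan2 of the mean
sine and cosine, and the spread is the root-mean-square of deviations from
that mean, each wrapped into (−180°, 180°]. For the tight clusters seen in
glycan surveys (spreads of 10–25°, far from the seam) this coincides with
arithmetic mean ± SD to well under a degree, which is why either reading of
a published "mean ± SD" is compatible with this implementation. A perfectly
uniform sample (zero resultant) has no mean direction and raises an error
rather than returning an arbitrary value.

## Connectivity from geometry

Structure files are read through bio3d (PDB and mmCIF); model 1 only, and a
single alternate-location conformer (blank or "A" by default,
configurable). Carbohydrate connectivity is *inferred from geometry*, never
from LINK/CONECT records: a glycosidic linkage is an anomeric C1 within
1.8 Å of another sugar's exocyclic O2/O3/O4/O6. The 1.8 Å cutoff tolerates
the distorted bonds of low-resolution structures (C–O is ideally ≈1.41 Å).
Two guards keep inference honest in degenerate geometry:

* a residue that still carries its own O1 is a free reducing end and never
  donates (chemically, glycosylation replaces O1 with the bridge oxygen);
* when several oxygens fall inside the cutoff (possible in distorted or
  self-intersecting conformers), the one whose distance is closest to the
  ideal 1.41 Å bond length is taken; two candidates within 0.05 Å of the
  same score raise an ambiguity error naming the residues.

Sugar residues are recognised by canonical ring atom names (C1..C5, O5, all
present, mutually within 1.9 Å around the ring); there is no graph-based
ring perception. This is sufficient for standard PDB carbohydrate
components and is a documented limitation for exotic nomenclature.
Component codes map to sugar class and anomeric configuration through a
built-in dictionary (NAG/NDG/MAN/BMA/GAL/GLA/FUC); unknown codes with a
complete ring are admitted as class "other" with anomeric configuration
"unknown".

Trees are rooted at the reducing end (the residue that never donates).
Motif matching then binds roles by topology: the core mannose with an α1–3
and an α1–6 mannose child, each carrying a β1–2 GlcNAc; the bisecting
GlcNAc is a β1–4 GlcNAc child of the core; the chitobiose stem, terminal
galactose and core fucose are bound when present. Two candidate cores in
one tree is an ambiguity error.

## Geometric evidence checks

Crystal structures of glycans carry no hydrogens, so the NOE-reporter
distances are computed on reconstructed protons: each ring CH hydrogen is
placed along the negative vector sum of unit vectors from the carbon to its
heavy neighbours at C–H = 1.09 Å (the tetrahedral-bisector construction);
the GlcNAc amide hydrogen sits in the amide plane anti to the carbonyl
oxygen at N–H = 1.01 Å. This approximates what molecular-graphics programs
do when "adding hydrogens", hence distances quoted from crystal structures
are reproduced to a few tenths of an Ångström rather than exactly.

Default thresholds, all configurable through `glycanfold_config()`:

| parameter | default | rationale |
|---|---|---|
| classification cutoff | 45° | the published classification rule |
| NOE observability | 5.0 Å | standard upper bound for observable NOEs |
| H-bond donor–acceptor | 3.5 Å | usual heavy-atom criterion at 2–3 Å resolution |
| H-bond D–H…A angle | 120° | applied only when H coordinates exist |
| clash tolerance | 0.4 Å | common contact-analysis allowance on Bondi radii |
| histogram bin width | 15° | granularity of the survey histograms |

Hydrogen-bond donors are hydroxyl oxygens (exactly one covalent neighbour)
and amide nitrogens; acceptors are any O or N; covalently bonded and 1–3
pairs are excluded. Clash detection reports non-bonded pairs (1–2 and 1–3
excluded) closer than the Bondi-radius sum minus the tolerance.

Superposition is the Kabsch least-squares fit via singular value
decomposition with the determinant correction that forbids reflections;
fewer than three pairs or collinear fitting atoms raise a degeneracy error.
Model extension superposes a donor glycan onto a truncated one over the
ring atoms of their shared motif roles and grafts the donor residues whose
roles the truncated structure lacks (typically the chitobiose stem),
optionally counting clashes of the grafted atoms against an environment.

## The synthetic builder and what it does (not) establish

The builder generates coordinates from internal coordinates: ideal ⁴C₁
chairs (uniform 1.50 Å ring bonds, 111° ring angles, substituents on exact
tetrahedral directions, axial/equatorial per each sugar's stereochemistry),
docked residue by residue so that every glycosidic linkage has C1–O =
1.41 Å, C–O–C = 117° and exactly the requested φ/ψ(/ω). D-handedness is
fixed by the rotamer identity ω(O5) = ω(C4) − 120°, and α-L-fucose is built
as the mirror image of α-D-galactose without O6. Acetamido and free
hydroxymethyl groups sit at fixed standard torsions (C7–N2–C2–C1 = 75°,
planar amide with O7 syn to C2; free ω = 60°, the *gg* rotamer); the
GlcNAcβ1–2Man and GlcNAcβ1–4Man defaults, (−107, −93) and (−76, 107), come
from force-field-minimised disaccharide geometry and were fixed once,
before any downstream distance was measured. Optional Gaussian coordinate
jitter (seeded) tests tolerance behaviour.

Because residues are rigid and ideal, builder output emulates the *torsion
content* of real structures, not their fine geometry: no ring-pucker
variation, no exocyclic rotamer relaxation, no thermal displacement. Two
consequences matter for interpreting tests:

* Idealised builds show a handful of benign short contacts around fixed
  exocyclic defaults; the *discriminating* clash signal — bisected extend-a
  builds clash between Man-4′ and the bisecting GlcNAc while back-fold
  builds do not — is robust to this background and is what the tests
  assert.
* The curated bisected survey entries (PDB 5AV7, 5AVA, 3VYK, 2DW2, 3SGK)
  and the two non-bisected Manα1–3Man outliers (1SLC, 1ZAG) are represented
  by *synthetic stand-ins* built at their published torsions
  (`synthetic_survey_specs()`, `synthetic_outlier_specs()`); where a value
  was never published, the survey cluster centre or the entry's reference
  conformer triple is used. Tests on these stand-ins verify that the full
  pipeline (parse → connectivity → motif → torsions → classification →
  statistics) reproduces the published numbers *at the published geometry*;
  they do not re-measure the depositions themselves, and quantities that
  depend on unpublished degrees of freedom (notably the Man-3 H1 ↔
  GlcNAc-5′ H1 distance, which runs through an unpublished β1–2 linkage)
  reproduce only to the fidelity of the builder defaults.

Round-trip precision: fixed-column PDB output carries three decimals, which
bounds recovered torsions at about 0.1°; the mmCIF writer carries six
decimals, and the 0.05° closure property (200 random specifications,
uniform torsions) runs through that path. Random-torsion conformers whose
branches interpenetrate so badly that a foreign oxygen sits at bonding
distance of an anomeric carbon are excluded from round-trip properties —
connectivity inference from geometry alone is ill-posed there for any
method.

## Representative copies and reports

When an asymmetric unit contains several copies of the glycan, all copies
are computed; a single representative per structure enters the survey
report, chosen by lowest mean B-factor over the motif residues (ties and
B-free synthetic files fall back to the first by chain order; policy
configurable and logged). Reports serialise as TSV (per linkage and per
glycan) and JSON (group statistics, class/rotamer counts, 0–360°
histograms at the configured bin width).

## Known limitations

* No graph-based ring perception; residues with non-canonical atom naming
  are skipped (logged).
* Torsions are profiled for the five core linkage types only; Galβ1–4 and
  Fucα1–6 extras are detected but not torsion-profiled.
* Hydrogen placement is a geometric approximation; published
  proton-distance values are matched to tenths of an Ångström, not exactly.
* The builder does no energy relaxation; its stand-ins are torsion-faithful
  idealisations, not replacements for deposited coordinates.
* Crystallographic lattice reconstruction (symmetry mates) is out of scope;
  analyses see the asymmetric unit as deposited.
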