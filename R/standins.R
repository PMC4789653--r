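# Synthetic stand-ins for the curated bisected-glycan survey.
#
# The five deposited bisected biantennary glycans (PDB 5AV7, 5AVA, 3VYK,
# 2DW2, 3SGK) and the two unusual non-bisected Mana1-3Man outliers (1SLC
# glycan 354, 1ZAG chain A) are represented here by SYNTHETIC coordinates:
# ideal-geometry glycans built at the torsion angles reported for those
# entries (where a linkage's value was not reported, the survey cluster
# centre or the entry's reference-conformer triple is used). They reproduce
# the published torsions and conformer classes by construction and serve as
# self-contained fixtures for the full scan pipeline; they are NOT the
# deposited coordinates, and residue-level detail (ring pucker, exocyclic
# rotamers, thermal displacement) is idealised.

#' Synthetic stand-ins for the bisected-glycan survey entries
#'
#' @return named list (one element per entry id) of lists with `spec`
#'   (a `build_spec`), `bisected`, `source_category` and `a16`/`a13`, the
#'   torsions the stand-in was built at.
#' @export
synthetic_survey_specs <- function() {
  refs <- reference_conformers()
  ref_triple <- function(nm) {
    i <- match(nm, refs$name)
    c(refs$phi[i], refs$psi[i], refs$omega[i])
  }
  a13_bis <- c(82, -129)
  entry <- function(a16, a13, chitobiose, source_category) {
    list(spec = build_spec(biantennary_spec(
           a16 = a16, a13 = a13, bisected = TRUE, chitobiose = chitobiose)),
         bisected = TRUE, source_category = source_category,
         a16 = a16, a13 = a13)
  }
  list(
    # lectin-bound hexasaccharide; reported Mana1-6Man triple
    `5AV7_E` = entry(c(95, 105, 58), a13_bis, FALSE,
                     "lectin/antibody complex"),
    # lectin-bound octasaccharide with chitobiose stem
    `5AVA_A` = entry(c(55, 126, 63), a13_bis, TRUE,
                     "lectin/antibody complex"),
    # DCIR2-bound hexasaccharide, extend-b
    `3VYK` = entry(ref_triple("extend-b"), a13_bis, FALSE,
                   "lectin/antibody complex"),
    # glycoprotein N-glycan (chitobiose present), back-fold
    `2DW2` = entry(ref_triple("back-fold"), a13_bis, TRUE, "glycoprotein"),
    # Fc-domain N-glycan, extend-b
    `3SGK` = entry(ref_triple("extend-b"), a13_bis, TRUE, "glycoprotein")
  )
}

#' Synthetic stand-ins for the non-bisected Mana1-3Man outliers
#'
#' Non-bisected biantennary glycans built at the unusual Mana1-3Man torsions
#' reported for the galectin-1 complex (1SLC glycan 354) and
#' zinc-alpha-2-glycoprotein (1ZAG chain A).
#'
#' @return named list in the same layout as [synthetic_survey_specs()].
#' @export
synthetic_outlier_specs <- function() {
  entry <- function(a13, source_category) {
    a16 <- c(70, 180, 180)
    list(spec = build_spec(biantennary_spec(
           a16 = a16, a13 = a13, bisected = FALSE, chitobiose = FALSE)),
         bisected = FALSE, source_category = source_category,
         a16 = a16, a13 = a13)
  }
  list(`1SLC_354` = entry(c(88, -54), "lectin/antibody complex"),
       `1ZAG_A`  = entry(c(173, -60), "glycoprotein"))
}

#' Write the synthetic survey as PDB files with a manifest
#'
#' Builds every stand-in of [synthetic_survey_specs()] (and optionally the
#' outliers) and emits one PDB file per entry, named
#' `<id>_synthetic.pdb`.
#'
#' @param dir output directory (created if needed).
#' @param outliers also write the non-bisected outlier stand-ins?
#' @return manifest data.frame with columns `structure_id`, `path`,
#'   `bisected`, `source_category`.
#' @export
synthetic_survey_fixtures <- function(dir, outliers = FALSE) {
  specs <- synthetic_survey_specs()
  if (outliers) specs <- c(specs, synthetic_outlier_specs())
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rows <- lapply(names(specs), function(id) {
    path <- file.path(dir, paste0(id, "_synthetic.pdb"))
    emit_pdb(build_glycan(specs[[id]]$spec), path)
    data.frame(structure_id = id, path = path,
               bisected = specs[[id]]$bisected,
               source_category = specs[[id]]$source_category,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
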