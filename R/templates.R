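# Ideal monosaccharide templates.
#
# Each template is a pyranose in the 4C1 chair (1C4 for the L-sugar fucose),
# built analytically: a six-membered ring with uniform 1.50 A bonds and 111
# degree internal angles, substituents placed on the remaining tetrahedral
# directions (axial or equatorial per the sugar's stereochemistry), hydroxyl
# and N-acetyl geometry at standard bond lengths. Rings are rigid: only
# glycosidic torsions vary during building, which mirrors how crystallographic
# glycan conformers are compared.
#
# Handedness: for D-pyranoses the torsion of O6 about C5-C6 measured against
# O5 differs from that measured against C4 by -120 degrees (this is what makes
# gg/gt/tg come out as omega = 60/180/-60 against C4). The ring traversal
# O5 -> C1 -> ... -> C5 is therefore laid out clockwise when viewed from the
# beta face.

.glycanfold_cache <- new.env(parent = emptyenv())

# chain-extension bond lengths (A); uniform ring geometry
.BOND <- list(ring = 1.50, c_oh = 1.42, c1_o1 = 1.41, glyc_c1_o = 1.41,
              c5_c6 = 1.52, c6_o6 = 1.43, c_n = 1.47, n_c7 = 1.35,
              c7_o7 = 1.23, c7_c8 = 1.50, c_h = 1.09, n_h = 1.01)
.ANGLE <- list(ring = 111, glyc_c_o_c = 117, c5_c6_o6 = 111,
               c2_n2_c7 = 121, n2_c7_o7 = 123, n2_c7_c8 = 116)

# default exocyclic torsions (degrees), used where no linkage overrides them:
#   omega_c4  : free hydroxymethyl O6-C6-C5-C4 (gg rotamer)
#   c7_n2     : acetamido C7-N2-C2-C1 and planar amide with O7 syn to C2
.DEFAULT_EXO <- list(omega_c4 = 60, c7_n2_c2_c1 = 75, o7_c7_n2_c2 = 0,
                     c8_c7_n2_c2 = 180)

#' Sugar component dictionary
#'
#' Built-in table mapping PDB chemical-component codes to sugar class and
#' anomeric configuration for the residues that make up biantennary
#' N-glycans.
#'
#' @return data.frame with columns `component_id`, `sugar_class`
#'   (GlcNAc/Man/Gal/Fuc), `anomeric_config` (alpha/beta).
#' @export
sugar_dictionary <- function() {
  data.frame(
    component_id   = c("NAG", "NDG", "MAN", "BMA", "GAL", "GLA", "FUC"),
    sugar_class    = c("GlcNAc", "GlcNAc", "Man", "Man", "Gal", "Gal", "Fuc"),
    anomeric_config = c("beta", "alpha", "alpha", "beta", "beta", "alpha",
                        "alpha"),
    stringsAsFactors = FALSE
  )
}

# solve the symmetric chair: hexagon radius a, alternating height +-d,
# such that bond = 1.50 and internal angle = 111 degrees
chair_parameters <- function() {
  if (!is.null(.glycanfold_cache$chair)) return(.glycanfold_cache$chair)
  f <- function(par) {
    a <- par[1]; d <- par[2]
    p <- vapply(0:2, function(k)
      c(a * cos(k * pi / 3), -a * sin(k * pi / 3),
        if (k %% 2 == 0) d else -d), numeric(3))
    b <- vnorm(p[, 2] - p[, 1])
    an <- bond_angle(p[, 1], p[, 2], p[, 3])
    (b - .BOND$ring)^2 + (an - .ANGLE$ring)^2
  }
  sol <- stats::optim(c(1.25, 0.25), f, method = "Nelder-Mead",
                      control = list(reltol = 1e-15, maxit = 10000))
  .glycanfold_cache$chair <- sol$par
  sol$par
}

# ring coordinates, rownames O5,C1..C5; clockwise seen from +z (D-handedness)
chair_ring_coords <- function() {
  par <- chair_parameters()
  a <- par[1]; d <- par[2]
  p <- t(vapply(0:5, function(k)
    c(a * cos(k * pi / 3), -a * sin(k * pi / 3),
      if (k %% 2 == 0) d else -d), numeric(3)))
  rownames(p) <- c("O5", "C1", "C2", "C3", "C4", "C5")
  p
}

ring_mean_normal <- function(p) {
  ctr <- colMeans(p)
  n <- c(0, 0, 0)
  for (i in 1:6) {
    j <- if (i == 6) 1 else i + 1
    n <- n + vcross(p[i, ] - ctr, p[j, ] - ctr)
  }
  unitv(n)
}

# axial and equatorial unit directions at ring atom `at`
ring_substituent_dirs <- function(ring, at) {
  nb <- list(C1 = c("O5", "C2"), C2 = c("C1", "C3"), C3 = c("C2", "C4"),
             C4 = c("C3", "C5"), C5 = c("C4", "O5"))[[at]]
  td <- tetrahedral_directions(ring[at, ], ring[nb[1], ], ring[nb[2], ])
  nrm <- ring_mean_normal(ring)
  if (abs(sum(td$d1 * nrm)) > abs(sum(td$d2 * nrm)))
    list(axial = td$d1, equatorial = td$d2)
  else
    list(axial = td$d2, equatorial = td$d1)
}

# axial(TRUE)/equatorial(FALSE) of each substituent position, per sugar.
# Positions: O1 (anomeric), X2 (O2 or N2), O3, O4; C6 is equatorial at C5 in
# all residues handled here.
.SUGAR_AXIAL <- list(
  NAG = c(O1 = FALSE, X2 = FALSE, O3 = FALSE, O4 = FALSE),  # beta-D-GlcNAc
  NDG = c(O1 = TRUE,  X2 = FALSE, O3 = FALSE, O4 = FALSE),  # alpha-D-GlcNAc
  MAN = c(O1 = TRUE,  X2 = TRUE,  O3 = FALSE, O4 = FALSE),  # alpha-D-Man
  BMA = c(O1 = FALSE, X2 = TRUE,  O3 = FALSE, O4 = FALSE),  # beta-D-Man
  GAL = c(O1 = FALSE, X2 = FALSE, O3 = FALSE, O4 = TRUE),   # beta-D-Gal
  GLA = c(O1 = TRUE,  X2 = FALSE, O3 = FALSE, O4 = TRUE),   # alpha-D-Gal
  FUC = c(O1 = TRUE,  X2 = FALSE, O3 = FALSE, O4 = TRUE)    # alpha-L-Fuc (mirrored)
)

#' Ideal-geometry template for one sugar residue
#'
#' Returns the atoms of a single pyranose residue in an ideal chair with the
#' stereochemistry implied by the chemical-component code. GlcNAc templates
#' carry the full acetamido group (N2, C7, O7, C8); fucose is built as the
#' mirror image of alpha-D-galactose without O6 (6-deoxy-L-galactose).
#'
#' @param component_id one of NAG, NDG, MAN, BMA, GAL, GLA, FUC.
#' @return matrix of coordinates with atom-name rownames.
#' @export
sugar_template <- function(component_id) {
  key <- paste0("tmpl_", component_id)
  if (!is.null(.glycanfold_cache[[key]])) return(.glycanfold_cache[[key]])
  ax <- .SUGAR_AXIAL[[component_id]]
  if (is.null(ax)) stop("unknown sugar component: ", component_id)
  is_glcnac <- component_id %in% c("NAG", "NDG")
  is_fuc <- component_id == "FUC"
  ring <- chair_ring_coords()
  coords <- ring

  put <- function(name, pos) {
    coords <<- rbind(coords, matrix(pos, 1, 3, dimnames = list(name, NULL)))
  }
  sub_dir <- function(at, axial) {
    d <- ring_substituent_dirs(ring, at)
    if (axial) d$axial else d$equatorial
  }

  put("O1", ring["C1", ] + .BOND$c1_o1 * sub_dir("C1", ax[["O1"]]))
  if (is_glcnac) {
    put("N2", ring["C2", ] + .BOND$c_n * sub_dir("C2", ax[["X2"]]))
    put("C7", place_atom(coords["C1", ], ring["C2", ], coords["N2", ],
                         .BOND$n_c7, .ANGLE$c2_n2_c7, .DEFAULT_EXO$c7_n2_c2_c1))
    put("O7", place_atom(ring["C2", ], coords["N2", ], coords["C7", ],
                         .BOND$c7_o7, .ANGLE$n2_c7_o7, .DEFAULT_EXO$o7_c7_n2_c2))
    put("C8", place_atom(ring["C2", ], coords["N2", ], coords["C7", ],
                         .BOND$c7_c8, .ANGLE$n2_c7_c8, .DEFAULT_EXO$c8_c7_n2_c2))
  } else {
    put("O2", ring["C2", ] + .BOND$c_oh * sub_dir("C2", ax[["X2"]]))
  }
  put("O3", ring["C3", ] + .BOND$c_oh * sub_dir("C3", ax[["O3"]]))
  put("O4", ring["C4", ] + .BOND$c_oh * sub_dir("C4", ax[["O4"]]))
  put("C6", ring["C5", ] + .BOND$c5_c6 * sub_dir("C5", FALSE))
  if (!is_fuc) {
    put("O6", place_atom(ring["C4", ], ring["C5", ], coords["C6", ],
                         .BOND$c6_o6, .ANGLE$c5_c6_o6, .DEFAULT_EXO$omega_c4))
  }
  if (is_fuc) coords[, 1] <- -coords[, 1]  # mirror: D-Gal skeleton -> L-Fuc
  .glycanfold_cache[[key]] <- coords
  coords
}

element_of_atom <- function(name) {
  substr(gsub("^[0-9]*", "", name), 1, 1)
}
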