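# Geometric evidence checks: hydrogen placement, proton-proton (NOE)
# distances, hydrogen bonds, van der Waals clashes, and fragment grafting.
#
# Crystal structures of glycans carry no hydrogen positions, so aliphatic
# ring hydrogens are reconstructed from heavy-atom geometry: each ring CH
# proton sits along the negative vector sum of the unit vectors from the
# carbon to its heavy neighbours, at a C-H length of 1.09 A (the classic
# tetrahedral-bisector construction). Amide protons are placed in the amide
# plane anti to the carbonyl oxygen.

.BONDI_RADII <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47,
                  P = 1.80, S = 1.80)

heavy_neighbours <- function(xyz_all, names_all, center, cutoff = 1.75) {
  d <- sqrt(rowSums(sweep(xyz_all, 2, center)^2))
  i <- which(d > 1e-6 & d <= cutoff)
  i[!grepl("^H", names_all[i])]
}

#' Place ring and amide hydrogens on a sugar residue
#'
#' One hydrogen per ring carbon C1-C5 along the tetrahedral bisector of its
#' heavy neighbours (C-H 1.09 A); for GlcNAc, the amide hydrogen on N2 in
#' the amide plane anti to the carbonyl oxygen (N-H 1.01 A). Neighbours are
#' looked up geometrically, so glycosidic bridge oxygens on linked residues
#' are honoured when the full atom table is supplied as context.
#'
#' @param residue a `sugar_residue`.
#' @param context optional data.frame of all structure atoms (defaults to
#'   the residue's own atoms); supply the whole glycan to account for
#'   glycosidic substituents.
#' @return data.frame with columns `residue_key`, `parent_atom`, `h_name`,
#'   `x`, `y`, `z`; placement failures (a carbon with fewer than 2 or more
#'   than 3 heavy neighbours) are recorded in `attr(, "errors")` and skip
#'   only that atom.
#' @export
place_ring_hydrogens <- function(residue, context = NULL) {
  stopifnot(inherits(residue, "sugar_residue"))
  at <- residue$atoms
  if (is.null(context)) context <- at
  cxyz <- as.matrix(context[, c("x", "y", "z")])
  cnames <- context$elety
  errors <- character()
  rows <- list()
  for (cn in c("C1", "C2", "C3", "C4", "C5")) {
    cpos <- atom_xyz(at, cn)
    if (is.null(cpos)) next
    nb <- heavy_neighbours(cxyz, cnames, cpos)
    if (length(nb) < 2 || length(nb) > 3) {
      errors <- c(errors, sprintf("%s %s: %d heavy neighbours",
                                  residue$residue_key, cn, length(nb)))
      next
    }
    vsum <- c(0, 0, 0)
    for (i in nb) vsum <- vsum + unitv(cxyz[i, ] - cpos)
    h <- cpos - .BOND$c_h * unitv(vsum)
    rows[[length(rows) + 1]] <- data.frame(
      residue_key = residue$residue_key, parent_atom = cn,
      h_name = sub("C", "H", cn), x = h[1], y = h[2], z = h[3],
      stringsAsFactors = FALSE)
  }
  n2 <- atom_xyz(at, "N2")
  c2 <- atom_xyz(at, "C2")
  c7 <- atom_xyz(at, "C7")
  if (!is.null(n2) && !is.null(c2) && !is.null(c7)) {
    h <- n2 - .BOND$n_h * unitv(unitv(c2 - n2) + unitv(c7 - n2))
    rows[[length(rows) + 1]] <- data.frame(
      residue_key = residue$residue_key, parent_atom = "N2",
      h_name = "HN2", x = h[1], y = h[2], z = h[3],
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(residue_key = character(), parent_atom = character(),
               h_name = character(), x = numeric(), y = numeric(),
               z = numeric(), stringsAsFactors = FALSE)
  attr(out, "errors") <- errors
  out
}

all_graph_atoms <- function(graph) {
  do.call(rbind, lapply(graph$residues, `[[`, "atoms"))
}

#' Hydrogens for every residue of a glycan
#'
#' @param graph a `glycan_graph` (or `biantennary_motif`, whose graph is
#'   used).
#' @return combined hydrogen table as in [place_ring_hydrogens()].
#' @export
glycan_hydrogens <- function(graph) {
  if (inherits(graph, "biantennary_motif")) graph <- graph$graph
  ctx <- all_graph_atoms(graph)
  out <- do.call(rbind, lapply(graph$residues, place_ring_hydrogens,
                               context = ctx))
  rownames(out) <- NULL
  out
}

#' Default NOE-reporter proton pairs
#'
#' The two inter-residue proton pairs that discriminate back-fold from
#' extended conformers: Man-3 H1 to GlcNAc-5' H1, and Man-3 H1 to Man-4' H2.
#'
#' @return list of pair specifications (`role`/`h_name` pairs).
#' @export
default_noe_pairs <- function() {
  list(list(a = c(role = "man3", h = "H1"), b = c(role = "glcnac5p", h = "H1")),
       list(a = c(role = "man3", h = "H1"), b = c(role = "man4p", h = "H2")))
}

#' Proton-proton distances of a motif
#'
#' Places hydrogens and evaluates Euclidean distances for the requested
#' role/proton pairs; a pair is NOE-compatible when the distance does not
#' exceed the threshold.
#'
#' @param motif a `biantennary_motif`.
#' @param pairs list of pair specs as in [default_noe_pairs()].
#' @param threshold NOE observability threshold in Angstrom (default 5.0).
#' @return data.frame with columns `pair`, `distance`, `noe_compatible`;
#'   unresolvable pairs yield NA with a note in `attr(, "errors")`.
#' @export
proton_distances <- function(motif, pairs = default_noe_pairs(),
                             threshold = 5.0) {
  stopifnot(inherits(motif, "biantennary_motif"))
  hs <- glycan_hydrogens(motif$graph)
  errors <- character()
  hpos <- function(spec) {
    key <- motif$roles[[spec[["role"]]]]
    if (is.null(key)) return(NULL)
    i <- which(hs$residue_key == key & hs$h_name == spec[["h"]])
    if (length(i) != 1) return(NULL)
    as.numeric(hs[i, c("x", "y", "z")])
  }
  rows <- lapply(pairs, function(p) {
    lab <- sprintf("%s %s - %s %s", p$a[["role"]], p$a[["h"]],
                   p$b[["role"]], p$b[["h"]])
    pa <- hpos(p$a); pb <- hpos(p$b)
    if (is.null(pa) || is.null(pb)) {
      errors <<- c(errors, paste0("cannot resolve pair: ", lab))
      return(data.frame(pair = lab, distance = NA_real_,
                        noe_compatible = NA, stringsAsFactors = FALSE))
    }
    d <- vnorm(pa - pb)
    data.frame(pair = lab, distance = d, noe_compatible = d <= threshold,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "errors") <- errors
  out
}

bond_list <- function(xyz, elems, cutoff_heavy = 1.75) {
  n <- nrow(xyz)
  bonds <- vector("list", n)
  if (n < 2) return(bonds)
  d <- as.matrix(stats::dist(xyz))
  for (i in seq_len(n)) {
    cut <- ifelse(grepl("^H", elems[i]) | grepl("^H", elems), 1.3,
                  cutoff_heavy)
    bonds[[i]] <- which(d[i, ] > 1e-6 & d[i, ] <= cut)
  }
  bonds
}

excluded_pairs <- function(bonds) {
  # 1-2 and 1-3 neighbour sets per atom index
  n <- length(bonds)
  ex <- vector("list", n)
  for (i in seq_len(n)) {
    one3 <- unique(unlist(lapply(bonds[[i]], function(j) bonds[[j]])))
    ex[[i]] <- unique(c(bonds[[i]], one3))
  }
  ex
}

#' Detect hydrogen bonds among sugar atoms
#'
#' Donor-acceptor pairs by heavy-atom distance: donors are hydroxyl oxygens
#' (one covalent neighbour) and amide nitrogens; acceptors are any oxygen or
#' nitrogen. Covalently bonded and 1-3 pairs are excluded. When hydrogen
#' coordinates are supplied, the D-H...A angle criterion is applied as well;
#' crystal-structure workflows typically run distance-only.
#'
#' @param atoms data.frame of atoms (layout as in `glycan_structure$atoms`).
#' @param heavy_cutoff donor-acceptor distance cutoff in Angstrom
#'   (default 3.5).
#' @param angle_min minimum D-H...A angle in degrees (default 120), used
#'   only for donors with an available hydrogen.
#' @param hydrogens optional hydrogen table from [glycan_hydrogens()].
#' @return data.frame with columns `donor_key`, `donor_atom`,
#'   `acceptor_key`, `acceptor_atom`, `heavy_distance`, `angle` (NA without
#'   hydrogen).
#' @export
detect_hbonds <- function(atoms, heavy_cutoff = 3.5, angle_min = 120,
                          hydrogens = NULL) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  keys <- residue_keys(atoms)
  names_ <- atoms$elety
  elems <- ifelse(nchar(atoms$elesy) > 0, atoms$elesy,
                  element_of_atom(names_))
  bonds <- bond_list(xyz, names_)
  ex <- excluded_pairs(bonds)
  ncov <- vapply(bonds, length, integer(1))
  is_donor <- (elems == "O" & ncov == 1 & names_ != "O7") |
              (elems == "N" & names_ == "N2")
  is_acc <- elems %in% c("O", "N")
  rows <- list()
  for (i in which(is_donor)) {
    for (j in which(is_acc)) {
      if (j == i || j %in% ex[[i]]) next
      dij <- vnorm(xyz[i, ] - xyz[j, ])
      if (dij > heavy_cutoff) next
      ang <- NA_real_
      if (!is.null(hydrogens)) {
        hi <- which(hydrogens$residue_key == keys[i] &
                      hydrogens$parent_atom == names_[i])
        if (length(hi) == 1) {
          h <- as.numeric(hydrogens[hi, c("x", "y", "z")])
          ang <- bond_angle(xyz[i, ], h, xyz[j, ])
          if (ang < angle_min) next
        }
      }
      rows[[length(rows) + 1]] <- data.frame(
        donor_key = keys[i], donor_atom = names_[i],
        acceptor_key = keys[j], acceptor_atom = names_[j],
        heavy_distance = dij, angle = ang, stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(donor_key = character(), donor_atom = character(),
               acceptor_key = character(), acceptor_atom = character(),
               heavy_distance = numeric(), angle = numeric(),
               stringsAsFactors = FALSE)
}

#' Detect van der Waals clashes
#'
#' Reports every non-bonded atom pair (1-2 and 1-3 neighbours excluded)
#' whose separation is smaller than the sum of Bondi radii minus a
#' tolerance.
#'
#' @param atoms data.frame of atoms.
#' @param vdw_table named vector of van der Waals radii by element (default:
#'   Bondi).
#' @param tolerance clash tolerance in Angstrom (default 0.4).
#' @return data.frame with columns `key_a`, `atom_a`, `key_b`, `atom_b`,
#'   `distance`, `overlap` (positive for every reported pair).
#' @export
detect_clashes <- function(atoms, vdw_table = .BONDI_RADII, tolerance = 0.4) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  keys <- residue_keys(atoms)
  names_ <- atoms$elety
  elems <- ifelse(nchar(atoms$elesy) > 0, atoms$elesy,
                  element_of_atom(names_))
  unknown <- setdiff(unique(elems), names(vdw_table))
  if (length(unknown))
    stop("element(s) missing from van der Waals table: ",
         paste(unknown, collapse = ", "))
  r <- vdw_table[elems]
  bonds <- bond_list(xyz, names_)
  ex <- excluded_pairs(bonds)
  n <- nrow(xyz)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (j %in% ex[[i]]) next
      dij <- vnorm(xyz[i, ] - xyz[j, ])
      ov <- r[i] + r[j] - tolerance - dij
      if (ov > 0)
        rows[[length(rows) + 1]] <- data.frame(
          key_a = keys[i], atom_a = names_[i],
          key_b = keys[j], atom_b = names_[j],
          distance = dij, overlap = as.numeric(ov),
          stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(key_a = character(), atom_a = character(),
               key_b = character(), atom_b = character(),
               distance = numeric(), overlap = numeric(),
               stringsAsFactors = FALSE)
}

# clashes restricted to pairs with one atom in each residue-key set
clashes_between <- function(clashes, keys_a, keys_b) {
  sel <- (clashes$key_a %in% keys_a & clashes$key_b %in% keys_b) |
         (clashes$key_a %in% keys_b & clashes$key_b %in% keys_a)
  clashes[sel, , drop = FALSE]
}

#' Graft missing residues from a donor structure
#'
#' Superposes a donor glycan onto a truncated glycan over the ring atoms of
#' their shared motif residues (Kabsch fit), then grafts the donor residues
#' whose roles are absent from the truncated motif (e.g. the chitobiose
#' stem). Optionally counts clashes of the grafted atoms against an
#' environment.
#'
#' @param truncated `biantennary_motif` of the structure to extend.
#' @param donor `biantennary_motif` providing the missing residues.
#' @param shared_roles roles used for fitting; default: all roles bound in
#'   both motifs.
#' @param environment optional data.frame of surrounding atoms for clash
#'   counting.
#' @param tolerance clash tolerance passed to [detect_clashes()].
#' @return list with `atoms` (truncated atoms plus transformed grafted
#'   atoms), `grafted_keys`, `superposition`, and `environment_clashes`
#'   (NULL without an environment).
#' @export
model_extension <- function(truncated, donor, shared_roles = NULL,
                            environment = NULL, tolerance = 0.4) {
  stopifnot(inherits(truncated, "biantennary_motif"),
            inherits(donor, "biantennary_motif"))
  if (is.null(shared_roles))
    shared_roles <- intersect(names(truncated$roles), names(donor$roles))
  if (length(shared_roles) == 0)
    stop("superposition is degenerate: no shared roles between structures")
  ring_of <- function(motif, role)
    motif$graph$residues[[motif$roles[[role]]]]$ring
  mob <- do.call(rbind, lapply(shared_roles, ring_of, motif = donor))
  tgt <- do.call(rbind, lapply(shared_roles, ring_of, motif = truncated))
  sp <- superpose(mob, tgt)
  graft_roles <- setdiff(names(donor$roles), names(truncated$roles))
  graft_keys <- unlist(donor$roles[graft_roles], use.names = FALSE)
  donor_atoms <- all_graph_atoms(donor$graph)
  g_at <- donor_atoms[residue_keys(donor_atoms) %in% graft_keys, ,
                      drop = FALSE]
  base <- all_graph_atoms(truncated$graph)
  if (nrow(g_at)) {
    moved <- apply_superposition(as.matrix(g_at[, c("x", "y", "z")]), sp)
    g_at$x <- moved[, 1]; g_at$y <- moved[, 2]; g_at$z <- moved[, 3]
    # keep grafted residue keys distinct from the target structure's
    free_chain <- setdiff(LETTERS, unique(base$chain))[1]
    g_at$chain <- free_chain
  }
  combined <- rbind(base, g_at)
  rownames(combined) <- NULL
  env_clashes <- NULL
  if (!is.null(environment) && nrow(g_at)) {
    pool <- rbind(g_at, environment)
    cl <- detect_clashes(pool, tolerance = tolerance)
    env_clashes <- clashes_between(cl, unique(residue_keys(g_at)),
                                   unique(residue_keys(environment)))
  }
  list(atoms = combined, grafted_keys = unique(residue_keys(g_at)),
       superposition = sp, environment_clashes = env_clashes)
}
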