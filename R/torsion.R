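# Biantennary motif recognition and glycosidic torsion computation.
#
# Residue roles follow the conventional numbering of complex-type N-glycans:
# GlcNAc-1/2 (chitobiose stem), Man-3 (core), Man-4 / GlcNAc-5 (alpha1-3
# branch), Man-4' / GlcNAc-5' (alpha1-6 branch), GlcNAc-7 (bisecting).

#' Locate the biantennary core motif in a glycan tree
#'
#' Searches for the branching unit GlcNAcb1-2Mana1-3[GlcNAcb1-2Mana1-6]Man.
#' The bisecting GlcNAc (b1-4 on the core mannose), the chitobiose stem and
#' terminal extras (galactose on GlcNAc-5', core fucose) are bound when
#' present.
#'
#' @param glycan a `glycan_graph`.
#' @return a `biantennary_motif` (list with `roles`: named residue keys,
#'   `bisected` flag, `graph`), or `NULL` when the motif is absent.
#' @export
find_biantennary_motif <- function(glycan) {
  stopifnot(inherits(glycan, "glycan_graph"))
  res <- glycan$residues
  kids <- function(key) {
    ch <- glycan$children[[key]]
    if (is.null(ch)) list() else ch
  }
  child_of <- function(key, position, config, class) {
    hits <- Filter(function(l)
      l$acceptor_position == position &&
        (is.na(config) || l$anomeric_config == config) &&
        res[[l$donor]]$sugar_class == class, kids(key))
    if (length(hits) == 1) hits[[1]]$donor else NULL
  }

  candidates <- list()
  for (key in names(res)) {
    if (res[[key]]$sugar_class != "Man") next
    man4 <- child_of(key, 3, "alpha", "Man")
    man4p <- child_of(key, 6, "alpha", "Man")
    if (is.null(man4) || is.null(man4p)) next
    g5 <- child_of(man4, 2, "beta", "GlcNAc")
    g5p <- child_of(man4p, 2, "beta", "GlcNAc")
    if (is.null(g5) || is.null(g5p)) next
    roles <- list(man3 = key, man4 = man4, man4p = man4p,
                  glcnac5 = g5, glcnac5p = g5p)
    g7 <- child_of(key, 4, "beta", "GlcNAc")
    if (!is.null(g7)) roles$glcnac7 <- g7
    # chitobiose stem: the core mannose donates b1-4 into GlcNAc-2
    don <- Filter(function(l) l$donor == key, glycan$linkages)
    if (length(don) == 1 && don[[1]]$acceptor_position == 4 &&
        res[[don[[1]]$acceptor]]$sugar_class == "GlcNAc") {
      roles$glcnac2 <- don[[1]]$acceptor
      don2 <- Filter(function(l) l$donor == roles$glcnac2, glycan$linkages)
      if (length(don2) == 1 && don2[[1]]$acceptor_position == 4 &&
          res[[don2[[1]]$acceptor]]$sugar_class == "GlcNAc")
        roles$glcnac1 <- don2[[1]]$acceptor
    }
    gal <- child_of(g5p, 4, "beta", "Gal")
    if (!is.null(gal)) roles$gal6p <- gal
    if (!is.null(roles$glcnac1)) {
      fuc <- child_of(roles$glcnac1, 6, "alpha", "Fuc")
      if (!is.null(fuc)) roles$fuc1 <- fuc
    }
    candidates[[length(candidates) + 1]] <- roles
  }
  if (length(candidates) == 0) return(NULL)
  if (length(candidates) > 1)
    stop("ambiguous biantennary motif: two candidate core mannoses (",
         paste(vapply(candidates, `[[`, "", "man3"), collapse = ", "), ")")
  structure(list(roles = candidates[[1]],
                 bisected = !is.null(candidates[[1]]$glcnac7),
                 graph = glycan),
            class = "biantennary_motif")
}

#' @export
print.biantennary_motif <- function(x, ...) {
  cat("Biantennary motif (", if (x$bisected) "bisected" else "non-bisected",
      ")\n", sep = "")
  for (r in names(x$roles)) cat(sprintf("  %-9s %s\n", r, x$roles[[r]]))
  invisible(x)
}

# the five torsion-profiled linkage types of the core motif:
# donor role, acceptor role, acceptor position, type code
.MOTIF_LINKAGES <- list(
  list(donor = "glcnac5",  acceptor = "man4",  pos = 2, type = "b1-2",
       tag = "GlcNAc(b1-2)Man-4"),
  list(donor = "glcnac5p", acceptor = "man4p", pos = 2, type = "b1-2",
       tag = "GlcNAc(b1-2)Man-4'"),
  list(donor = "man4",     acceptor = "man3",  pos = 3, type = "a1-3",
       tag = "Man(a1-3)Man"),
  list(donor = "man4p",    acceptor = "man3",  pos = 6, type = "a1-6",
       tag = "Man(a1-6)Man"),
  list(donor = "glcnac7",  acceptor = "man3",  pos = 4, type = "b1-4",
       tag = "GlcNAc(b1-4)Man")
)

#' Glycosidic torsions of a biantennary motif
#'
#' Computes phi/psi (and omega for the 1-6 linkage) for every linkage of the
#' core motif present, with the atom quadruples:
#' phi = O5-C1-O-Cx', psi = C1-O-Cx'-C(x-1)', omega = O-C6'-C5'-C4'
#' (unprimed atoms on the donor residue, primed on the acceptor; the
#' psi reference carbon is C1' for 1-2, C2' for 1-3, C3' for 1-4 and C5'
#' for 1-6 linkages).
#'
#' @param motif a `biantennary_motif`.
#' @return data.frame (the torsion set) with columns `linkage_label`,
#'   `linkage_type`, `phi`, `psi`, `omega` (NA except for 1-6), all angles
#'   in degrees in (-180, 180]. Per-linkage failures (missing atoms) are
#'   recorded in `attr(, "errors")` and yield NA angles; the remaining
#'   linkages are still computed.
#' @export
linkage_torsions <- function(motif) {
  stopifnot(inherits(motif, "biantennary_motif"))
  res <- motif$graph$residues
  errors <- character()
  rows <- lapply(.MOTIF_LINKAGES, function(lk) {
    dk <- motif$roles[[lk$donor]]
    ak <- motif$roles[[lk$acceptor]]
    if (is.null(dk) || is.null(ak)) return(NULL)
    la <- .LINK_ATOMS[[as.character(lk$pos)]]
    d <- res[[dk]]$atoms
    a <- res[[ak]]$atoms
    row <- data.frame(linkage_label = lk$tag, linkage_type = lk$type,
                      phi = NA_real_, psi = NA_real_, omega = NA_real_,
                      donor_key = dk, acceptor_key = ak,
                      stringsAsFactors = FALSE)
    o5 <- atom_xyz(d, "O5"); c1 <- atom_xyz(d, "C1")
    ob <- atom_xyz(a, la$o); cx <- atom_xyz(a, la$cx)
    cp <- atom_xyz(a, la$cprev)
    need <- list(O5 = o5, C1 = c1, O = ob, Cx = cx, Cprev = cp)
    if (any(vapply(need, is.null, logical(1)))) {
      errors <<- c(errors, paste0(lk$tag, ": missing atom ",
                                  paste(names(need)[vapply(need, is.null,
                                                           logical(1))],
                                        collapse = ",")))
      return(row)
    }
    row$phi <- dihedral(o5, c1, ob, cx)
    row$psi <- dihedral(c1, ob, cx, cp)
    if (lk$pos == 6) {
      c4a <- atom_xyz(a, "C4")
      if (is.null(c4a)) {
        errors <<- c(errors, paste0(lk$tag, ": missing atom C4'"))
      } else {
        row$omega <- dihedral(ob, cx, cp, c4a)
      }
    }
    row
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  attr(out, "errors") <- errors
  out
}

#' Omega rotamer classification
#'
#' Bins an omega torsion (O-C6'-C5'-C4' convention) to the nearest of the
#' three staggered rotamers: gg (60), gt (180), tg (300, i.e. -60). Class
#' boundaries fall at 0, 120 and 240 degrees; an input exactly on a boundary
#' resolves to the class with the smaller canonical angle in the order
#' gg < gt < tg.
#'
#' @param omega numeric vector of angles in degrees.
#' @return character vector of rotamer labels (`"gg"`, `"gt"`, `"tg"`).
#' @export
omega_rotamer <- function(omega) {
  stopifnot(all(is.finite(omega)))
  canon <- c(gg = 60, gt = 180, tg = -60)
  vapply(omega, function(w) {
    d <- abs(wrap_angle(w - canon))
    names(canon)[which(d == min(d))[1]]
  }, character(1))
}

#' Write a torsion table as TSV
#'
#' @param torsions data.frame as returned by [linkage_torsions()], possibly
#'   with added identifier columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_torsions <- function(torsions, path) {
  utils::write.table(torsions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
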