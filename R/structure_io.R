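# Reading structures and recovering carbohydrate connectivity.
#
# Connectivity is inferred from geometry alone (anomeric C1 to acceptor
# oxygen within a covalent cutoff); LINK/CONECT records are ignored, so the
# same code path serves deposited structures and builder output alike.

#' Parse a PDB or mmCIF structure
#'
#' Reads all ATOM/HETATM records of the first model through bio3d, resolving
#' alternate locations to a single configured conformer.
#'
#' @param path path to the structure file.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension;
#'   `.cif`/`.mmcif` are mmCIF, anything else PDB).
#' @param alt_loc alternate-location indicator to keep besides blank
#'   (default `"A"`).
#' @return object of class `glycan_structure`: list with `atoms` (data.frame
#'   with columns eleno, elety, alt, resid, chain, resno, insert, x, y, z,
#'   o, b, elesy), `path`, `format`.
#' @export
parse_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                            alt_loc = "A") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (format == "auto") {
    format <- if (grepl("\\.(cif|mmcif)$", path, ignore.case = TRUE))
      "mmcif" else "pdb"
  }
  parsed <- tryCatch(
    if (format == "pdb") bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
    else bio3d::read.cif(path, verbose = FALSE),
    error = function(e) stop("cannot parse ", path, " as ", format, ": ",
                             conditionMessage(e), call. = FALSE))
  at <- parsed$atom
  if (is.null(at) || nrow(at) == 0) stop("no atoms in ", path)
  alt <- at$alt
  keep <- is.na(alt) | alt == "" | alt == alt_loc
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0) stop("no atoms left after alt-loc filtering in ", path)
  atoms <- data.frame(
    eleno = at$eleno, elety = at$elety,
    alt = ifelse(is.na(at$alt), "", at$alt),
    resid = at$resid, chain = ifelse(is.na(at$chain), "", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o), b = ifelse(is.na(at$b), 0, at$b),
    elesy = if (!is.null(at$elesy)) at$elesy else element_of_atom(at$elety),
    stringsAsFactors = FALSE)
  bad <- !is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)
  if (any(bad)) stop("non-finite coordinates in ", path)
  structure(list(atoms = atoms, path = path, format = format),
            class = "glycan_structure")
}

#' @export
print.glycan_structure <- function(x, ...) {
  cat(sprintf("Structure %s (%s): %d atoms, %d residues\n",
              x$path, x$format, nrow(x$atoms),
              length(unique(residue_keys(x$atoms)))))
  invisible(x)
}

residue_keys <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, sep = ":")
}

.RING_ATOMS <- c("C1", "C2", "C3", "C4", "C5", "O5")

atom_xyz <- function(atoms, name) {
  i <- which(atoms$elety == name)
  if (length(i) == 0) return(NULL)
  as.numeric(atoms[i[1], c("x", "y", "z")])
}

#' Identify sugar residues in a structure
#'
#' Finds every residue with a complete pyranose ring by canonical atom names
#' (C1..C5, O5) whose ring atoms are mutually within covalent distance.
#' Residues with known chemical-component codes get their sugar class and
#' anomeric configuration from the dictionary; unknown codes with a complete
#' ring are admitted as class `"other"`. Residues with a recognised code but
#' an incomplete ring are skipped with a message.
#'
#' @param structure a `glycan_structure` (or bare atom data.frame).
#' @param dictionary component dictionary, see [sugar_dictionary()].
#' @param ring_cutoff maximum ring bond length in Angstrom (default 1.9,
#'   generous for low-resolution geometry).
#' @return list of `sugar_residue` objects; skipped residue keys in
#'   `attr(, "skipped")`.
#' @export
identify_sugars <- function(structure, dictionary = sugar_dictionary(),
                            ring_cutoff = 1.9) {
  atoms <- if (inherits(structure, "glycan_structure")) structure$atoms
           else structure
  keys <- residue_keys(atoms)
  out <- list()
  skipped <- character()
  for (k in unique(keys)) {
    res_at <- atoms[keys == k, , drop = FALSE]
    comp <- res_at$resid[1]
    known <- comp %in% dictionary$component_id
    have_ring <- all(.RING_ATOMS %in% res_at$elety)
    if (!have_ring) {
      if (known) {
        skipped <- c(skipped, k)
        message("skipping ", comp, " ", k, ": incomplete pyranose ring")
      }
      next
    }
    ring <- t(vapply(.RING_ATOMS, function(a) atom_xyz(res_at, a), numeric(3)))
    ord <- c("C1", "C2", "C3", "C4", "C5", "O5")
    closed <- all(vapply(1:6, function(i) {
      j <- if (i == 6) 1 else i + 1
      vnorm(ring[ord[i], ] - ring[ord[j], ]) <= ring_cutoff
    }, logical(1)))
    if (!closed) {
      if (known) {
        skipped <- c(skipped, k)
        message("skipping ", comp, " ", k, ": ring atoms not covalently closed")
      }
      next
    }
    di <- match(comp, dictionary$component_id)
    exo <- intersect(c("O1", "O2", "O3", "O4", "O6"), res_at$elety)
    out[[k]] <- structure(list(
      residue_key = k,
      component_id = comp,
      sugar_class = if (known) dictionary$sugar_class[di] else "other",
      anomeric_config = if (known) dictionary$anomeric_config[di] else "unknown",
      anomeric_carbon = "C1",
      ring = ring,
      exocyclic_oxygens = exo,
      atoms = res_at,
      mean_b = mean(res_at$b)), class = "sugar_residue")
  }
  attr(out, "skipped") <- skipped
  out
}

#' @export
print.sugar_residue <- function(x, ...) {
  cat(sprintf("%s (%s, %s) at %s: %d atoms\n", x$component_id, x$sugar_class,
              x$anomeric_config, x$residue_key, nrow(x$atoms)))
  invisible(x)
}

linkage_label <- function(donor_class, config, position, acceptor_class) {
  cfg <- switch(config, alpha = "a", beta = "b", "?")
  sprintf("%s(%s1-%d)%s", donor_class, cfg, position, acceptor_class)
}

#' Infer glycosidic linkages from geometry
#'
#' Emits a linkage for every anomeric carbon (donor C1) lying within the
#' covalent cutoff of another sugar's exocyclic oxygen O2/O3/O4/O6. The
#' acceptor position is read from the bridging oxygen's name and the
#' anomeric configuration from the donor's component code (geometric
#' fallback: `"unknown"` for class-`other` donors). When several oxygens
#' fall inside the cutoff, the one whose distance is closest to an ideal
#' C-O bond length (1.41 A) is taken as the covalent partner;
#' indistinguishable candidates raise an ambiguity error.
#'
#' @param sugars list of `sugar_residue` from [identify_sugars()].
#' @param cutoff covalent C1-O cutoff in Angstrom (default 1.8).
#' @return list of `glycosidic_linkage` objects (fields `donor`, `acceptor`,
#'   `acceptor_position`, `anomeric_config`, `linkage_label`).
#' @export
infer_linkages <- function(sugars, cutoff = 1.8) {
  links <- list()
  keys <- names(sugars)
  for (dk in keys) {
    d <- sugars[[dk]]
    c1 <- atom_xyz(d$atoms, d$anomeric_carbon)
    # a residue still carrying its own anomeric oxygen is a free reducing
    # end: glycosylation replaces O1 with the acceptor's bridge oxygen
    o1 <- atom_xyz(d$atoms, "O1")
    if (!is.null(o1) && vnorm(c1 - o1) < 1.6) next
    hits <- list()
    for (ak in keys) {
      if (ak == dk) next
      a <- sugars[[ak]]
      for (oname in intersect(c("O2", "O3", "O4", "O6"), a$exocyclic_oxygens)) {
        o <- atom_xyz(a$atoms, oname)
        if (vnorm(c1 - o) <= cutoff)
          hits[[length(hits) + 1]] <- list(acceptor = ak, oname = oname)
      }
    }
    if (length(hits) > 1) {
      # several oxygens inside the cutoff (possible in distorted or
      # self-intersecting conformers): the covalent partner is the one whose
      # separation is closest to an ideal C-O bond (1.41 A);
      # indistinguishable candidates are a genuine ambiguity
      sc <- vapply(hits, function(h)
        abs(vnorm(c1 - atom_xyz(sugars[[h$acceptor]]$atoms, h$oname)) - 1.41),
        numeric(1))
      ord <- order(sc)
      if (sc[ord[2]] - sc[ord[1]] < 0.05)
        stop("ambiguous glycosidic bond: C1 of ", dk,
             " has equally bond-like contacts to oxygens of ",
             paste(vapply(hits[ord[1:2]], `[[`, "", "acceptor"),
                   collapse = " and "))
      hits <- hits[ord[1]]
    }
    if (length(hits) == 1) {
      h <- hits[[1]]
      a <- sugars[[h$acceptor]]
      pos <- as.integer(substring(h$oname, 2))
      links[[length(links) + 1]] <- structure(list(
        donor = dk, acceptor = h$acceptor, acceptor_position = pos,
        anomeric_config = d$anomeric_config,
        linkage_label = linkage_label(d$sugar_class, d$anomeric_config,
                                      pos, a$sugar_class)),
        class = "glycosidic_linkage")
    }
  }
  links
}

#' Assemble glycan trees from residues and linkages
#'
#' Connected components become trees rooted at the residue whose anomeric
#' carbon is free (the reducing end or the protein-linked residue).
#'
#' @param sugars list of `sugar_residue`.
#' @param linkages list of `glycosidic_linkage` from [infer_linkages()].
#' @return list of `glycan_graph` objects, each with `residues` (named
#'   list), `linkages`, `root` (residue key) and `children` (named list:
#'   acceptor key -> list of donor linkages).
#' @export
assemble_glycans <- function(sugars, linkages) {
  keys <- names(sugars)
  donors <- vapply(linkages, `[[`, "", "donor")
  if (anyDuplicated(donors))
    stop("residue donates its anomeric carbon twice: ",
         paste(unique(donors[duplicated(donors)]), collapse = ", "))
  parent <- stats::setNames(rep(NA_character_, length(keys)), keys)
  for (l in linkages) parent[l$donor] <- l$acceptor

  # cycle check: follow parent pointers
  comp_root <- stats::setNames(rep(NA_character_, length(keys)), keys)
  for (k in keys) {
    seen <- character()
    cur <- k
    while (!is.na(parent[cur])) {
      if (cur %in% seen)
        stop("cycle detected among residues: ", paste(seen, collapse = ", "))
      seen <- c(seen, cur)
      cur <- parent[cur]
    }
    comp_root[k] <- cur
  }

  lapply(unique(comp_root), function(root) {
    members <- keys[comp_root == root]
    ln <- Filter(function(l) l$donor %in% members, linkages)
    children <- list()
    for (l in ln) children[[l$acceptor]] <- c(children[[l$acceptor]], list(l))
    structure(list(residues = sugars[members], linkages = ln,
                   root = root, children = children),
              class = "glycan_graph")
  })
}

#' @export
print.glycan_graph <- function(x, ...) {
  cat(sprintf("Glycan tree rooted at %s: %d residues, %d linkages\n",
              x$root, length(x$residues), length(x$linkages)))
  for (l in x$linkages)
    cat("  ", l$linkage_label, " (", l$donor, " -> ", l$acceptor, ")\n",
        sep = "")
  invisible(x)
}

#' Serialise a glycan graph to JSON
#'
#' @param graph a `glycan_graph`.
#' @return JSON string describing residues and linkages.
#' @export
glycan_graph_json <- function(graph) {
  res <- lapply(graph$residues, function(r)
    list(residue_key = r$residue_key, component_id = r$component_id,
         sugar_class = r$sugar_class, anomeric_config = r$anomeric_config))
  lnk <- lapply(graph$linkages, function(l)
    list(donor = l$donor, acceptor = l$acceptor,
         acceptor_position = l$acceptor_position,
         label = l$linkage_label))
  jsonlite::toJSON(list(root = graph$root, residues = unname(res),
                        linkages = unname(lnk)), auto_unbox = TRUE)
}

# all glycan graphs of a structure in one call
structure_glycans <- function(structure, dictionary = sugar_dictionary(),
                              linkage_cutoff = 1.8) {
  sugars <- identify_sugars(structure, dictionary)
  if (length(sugars) < 2) return(list())
  links <- infer_linkages(sugars, cutoff = linkage_cutoff)
  assemble_glycans(sugars, links)
}
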