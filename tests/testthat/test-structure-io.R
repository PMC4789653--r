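test_that("builder-emitted PDB parses with all residues and atoms", {
  b <- build_glycan(biantennary_spec(a16 = c(70, 90, 60), bisected = TRUE))
  f <- withr::local_tempfile(fileext = ".pdb")
  emit_pdb(b, f)
  st <- parse_structure(f)
  expect_s3_class(st, "glycan_structure")
  keys <- unique(glycanfold:::residue_keys(st$atoms))
  expect_length(keys, 6)
  counts <- table(glycanfold:::residue_keys(st$atoms))
  expect_true(all(counts >= 11))
  expect_equal(nrow(st$atoms), nrow(b$atoms))
})

test_that("PDB and mmCIF of the same model agree in atoms and coordinates", {
  b <- build_glycan(biantennary_spec(a16 = c(95, 105, 58), bisected = TRUE))
  fp <- withr::local_tempfile(fileext = ".pdb")
  fc <- withr::local_tempfile(fileext = ".cif")
  emit_pdb(b, fp)
  emit_mmcif(b, fc)
  sp <- parse_structure(fp)
  sc <- suppressWarnings(parse_structure(fc))
  expect_equal(nrow(sp$atoms), nrow(sc$atoms))
  expect_lt(max(abs(as.matrix(sp$atoms[, c("x", "y", "z")]) -
                    as.matrix(sc$atoms[, c("x", "y", "z")]))), 1e-3)
  expect_equal(sp$atoms$elety, sc$atoms$elety)
})

test_that("alternate locations resolve to a single conformer", {
  b <- build_glycan(biantennary_spec(a16 = c(70, 90, 60), bisected = FALSE))
  at <- b$atoms
  # duplicate one atom as alt-loc B, displaced
  dup <- at[1, ]
  dup$x <- dup$x + 0.5
  lines_a <- sprintf(
    "HETATM%5d  %-3s%s%s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$eleno, at$elety, ifelse(at$eleno == 1, "A", " "), at$resid, at$chain,
    at$resno, at$x, at$y, at$z, at$o, at$b, at$elesy)
  line_b <- sprintf(
    "HETATM%5d  %-3sB%s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    9999, dup$elety, dup$resid, dup$chain, dup$resno, dup$x, dup$y, dup$z,
    dup$o, dup$b, dup$elesy)
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(lines_a, line_b, "END"), f)
  st <- parse_structure(f)
  expect_equal(nrow(st$atoms), nrow(at))
  expect_false(any(st$atoms$alt == "B"))
})

test_that("parse errors are explicit", {
  expect_error(parse_structure(tempfile()), "not found")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines("REMARK nothing here", f)
  expect_error(parse_structure(f), "no atoms|cannot parse")
})

test_that("sugar identification orders ring atoms and skips broken rings", {
  b <- build_glycan(biantennary_spec(a16 = c(70, 90, 60), bisected = TRUE))
  f <- withr::local_tempfile(fileext = ".pdb")
  emit_pdb(b, f)
  st <- parse_structure(f)
  sugars <- identify_sugars(st)
  expect_length(sugars, 6)
  classes <- table(vapply(sugars, `[[`, "", "sugar_class"))
  expect_equal(as.integer(classes[["GlcNAc"]]), 3)
  expect_equal(as.integer(classes[["Man"]]), 3)
  for (s in sugars) {
    expect_equal(rownames(s$ring), c("C1", "C2", "C3", "C4", "C5", "O5"))
    # anomeric carbon bonded to ring oxygen
    expect_lt(glycanfold:::vnorm(s$ring["C1", ] - s$ring["O5", ]), 1.9)
  }

  # remove C4 of one NAG: that residue must be skipped, the rest survive
  at <- st$atoms
  nag_keys <- names(sugars)[vapply(sugars, function(s)
    s$component_id == "NAG", logical(1))]
  drop <- glycanfold:::residue_keys(at) == nag_keys[1] & at$elety == "C4"
  expect_message(
    sugars2 <- identify_sugars(st$atoms[!drop, , drop = FALSE]),
    "incomplete")
  expect_length(sugars2, 5)
  expect_true(nag_keys[1] %in% attr(sugars2, "skipped"))
})

test_that("protein-only structures contain no sugars", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.776   7.072  -4.983  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.007   7.899  -5.862  1.00  0.00           O",
    "END"), f)
  st <- parse_structure(f)
  expect_length(identify_sugars(st), 0)
})

test_that("linkage inference respects the covalent cutoff", {
  # two beta-GlcNAc templates joined C1...O4' at a controlled distance
  place_pair <- function(gap) {
    t1 <- sugar_template("NAG")
    t1 <- t1[rownames(t1) != "O1", ]  # donor C1 is glycosylated: no own O1
    t2 <- sugar_template("NAG")
    # move residue 2 so its O4 sits `gap` away from residue 1's C1 along x
    shift <- t1["C1", ] + c(gap, 0, 0) - t2["O4", ]
    t2 <- sweep(t2, 2, -shift)
    mk <- function(tm, resno) data.frame(
      eleno = seq_len(nrow(tm)), elety = rownames(tm), resid = "NAG",
      chain = "A", resno = resno, insert = "", x = tm[, 1], y = tm[, 2],
      z = tm[, 3], o = 1, b = 0, elesy = substr(rownames(tm), 1, 1),
      stringsAsFactors = FALSE)
    rbind(mk(t1, 1), mk(t2, 2))
  }
  near <- identify_sugars(place_pair(1.44))
  links <- infer_linkages(near)
  expect_length(links, 1)
  expect_equal(links[[1]]$acceptor_position, 4)
  expect_equal(links[[1]]$anomeric_config, "beta")
  expect_equal(links[[1]]$linkage_label, "GlcNAc(b1-4)GlcNAc")

  far <- identify_sugars(place_pair(3.0))
  expect_length(infer_linkages(far), 0)
})

test_that("linkage inference is invariant under rigid-body motion", {
  b <- build_glycan(biantennary_spec(a16 = c(70, 180, 60), bisected = TRUE))
  at <- b$atoms
  s1 <- identify_sugars(at)
  l1 <- infer_linkages(s1)
  moved <- at
  xyz <- random_rigid_transform(at[, c("x", "y", "z")], seed = 42)
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  l2 <- infer_linkages(identify_sugars(moved))
  lab <- function(l) sort(vapply(l, function(x)
    paste(x$donor, x$linkage_label, x$acceptor), ""))
  expect_equal(lab(l2), lab(l1))
})

test_that("glycan assembly yields trees with residues - components linkages", {
  b <- build_glycan(biantennary_spec(a16 = c(70, 90, 60), bisected = TRUE))
  sugars <- identify_sugars(b$atoms)
  links <- infer_linkages(sugars)
  expect_length(links, 5)
  labs <- sort(vapply(links, `[[`, "", "linkage_label"))
  expect_equal(labs, sort(c("GlcNAc(b1-2)Man", "GlcNAc(b1-2)Man",
                            "Man(a1-3)Man", "Man(a1-6)Man",
                            "GlcNAc(b1-4)Man")))
  trees <- assemble_glycans(sugars, links)
  expect_length(trees, 1)
  expect_length(trees[[1]]$linkages, length(trees[[1]]$residues) - 1)

  # two disjoint glycans -> two trees
  b2 <- build_glycan(glycan_node("MAN", children = list(
    glycan_node("MAN", 3, 80, -120, children = list(
      glycan_node("NAG", 2, -80, -100))))))
  at2 <- b2$atoms
  at2$resno <- at2$resno + 10
  at2$x <- at2$x + 50
  at2$eleno <- at2$eleno + 1000
  both <- rbind(b2$atoms, at2)
  trees2 <- assemble_glycans(identify_sugars(both),
                             infer_linkages(identify_sugars(both)))
  expect_length(trees2, 2)
  for (tr in trees2)
    expect_length(tr$linkages, length(tr$residues) - 1)
})

test_that("cycles and duplicated donors are rejected", {
  s <- identify_sugars(build_glycan(
    biantennary_spec(a16 = c(70, 90, 60), bisected = FALSE))$atoms)
  keys <- names(s)
  fake <- function(d, a, pos) structure(
    list(donor = d, acceptor = a, acceptor_position = pos,
         anomeric_config = "alpha", linkage_label = "x"),
    class = "glycosidic_linkage")
  expect_error(
    assemble_glycans(s, list(fake(keys[1], keys[2], 3),
                             fake(keys[2], keys[3], 3),
                             fake(keys[3], keys[1], 3))),
    "cycle")
  expect_error(
    assemble_glycans(s, list(fake(keys[1], keys[2], 3),
                             fake(keys[1], keys[3], 4))),
    "twice")
})

test_that("a C1 within reach of two acceptor oxygens is an ambiguity error", {
  t1 <- sugar_template("NAG")
  t1 <- t1[rownames(t1) != "O1", ]
  t2 <- sugar_template("NAG")
  t3 <- sugar_template("NAG")
  sh2 <- t1["C1", ] + c(1.44, 0, 0) - t2["O4", ]
  sh3 <- t1["C1", ] + c(-1.44, 0, 0) - t3["O6", ]
  t2 <- sweep(t2, 2, -sh2)
  t3 <- sweep(t3, 2, -sh3)
  mk <- function(tm, resno) data.frame(
    eleno = seq_len(nrow(tm)), elety = rownames(tm), resid = "NAG",
    chain = "A", resno = resno, insert = "", x = tm[, 1], y = tm[, 2],
    z = tm[, 3], o = 1, b = 0, elesy = substr(rownames(tm), 1, 1),
    stringsAsFactors = FALSE)
  sugars <- identify_sugars(rbind(mk(t1, 1), mk(t2, 2), mk(t3, 3)))
  expect_error(infer_linkages(sugars), "ambiguous")
  # a clearly closer oxygen wins without an error
  sh3b <- t1["C1", ] + c(-1.70, 0, 0) - t3["O6", ]
  t3b <- sweep(t3, 2, -sh3b)
  sugars2 <- identify_sugars(rbind(mk(t1, 1), mk(t2, 2), mk(t3b, 3)))
  links2 <- infer_linkages(sugars2)
  l1 <- Filter(function(l) l$donor == "A:1:", links2)
  expect_length(l1, 1)
  expect_equal(l1[[1]]$acceptor_position, 4)
})

test_that("glycan graphs serialise to JSON", {
  b <- build_glycan(biantennary_spec(a16 = c(70, 90, 60), bisected = TRUE))
  g <- assemble_glycans(identify_sugars(b$atoms),
                        infer_linkages(identify_sugars(b$atoms)))[[1]]
  j <- jsonlite::fromJSON(glycan_graph_json(g))
  expect_equal(nrow(j$residues), 6)
  expect_equal(nrow(j$linkages), 5)
  expect_equal(j$root, g$root)
})
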