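test_that("ring hydrogens sit at 1.09 A on tetrahedral bisectors", {
  b <- build_glycan(biantennary_spec(a16 = c(70, 90, 60), bisected = TRUE))
  g <- assemble_glycans(identify_sugars(b$atoms),
                        infer_linkages(identify_sugars(b$atoms)))[[1]]
  hs <- glycan_hydrogens(g)
  # one H per ring carbon C1-C5 plus one amide H per GlcNAc
  n_glcnac <- sum(vapply(g$residues, function(r)
    r$sugar_class == "GlcNAc", logical(1)))
  expect_equal(nrow(hs), 5 * length(g$residues) + n_glcnac)
  for (i in seq_len(nrow(hs))) {
    r <- g$residues[[hs$residue_key[i]]]
    parent <- glycanfold:::atom_xyz(r$atoms, hs$parent_atom[i])
    len <- glycanfold:::vnorm(as.numeric(hs[i, c("x", "y", "z")]) - parent)
    expect_equal(len, if (hs$parent_atom[i] == "N2") 1.01 else 1.09,
                 tolerance = 1e-6)
  }
})

test_that("bisector placement is exact on an analytic tetrahedral carbon", {
  # methane-like: three neighbours of a perfect tetrahedron; the fourth
  # vertex direction is the bisector solution
  tet <- rbind(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1)) / sqrt(3)
  at <- data.frame(
    eleno = 1:4, elety = c("C1", "O5", "C2", "O1"), resid = "MAN",
    chain = "A", resno = 1, insert = "",
    x = c(0, tet[, 1] * 1.4), y = c(0, tet[, 2] * 1.4),
    z = c(0, tet[, 3] * 1.4), o = 1, b = 0,
    elesy = c("C", "O", "C", "O"), stringsAsFactors = FALSE)
  fake <- structure(list(residue_key = "A:1:", atoms = at,
                         sugar_class = "Man"), class = "sugar_residue")
  hs <- place_ring_hydrogens(fake)
  expect_equal(nrow(hs), 1)
  h <- as.numeric(hs[1, c("x", "y", "z")])
  expect_equal(glycanfold:::unitv(h), -c(-1, -1, 1) / sqrt(3) * -1,
               tolerance = 1e-9)
  for (k in 1:3) {
    ang <- glycanfold:::bond_angle(h, c(0, 0, 0), tet[k, ] * 1.4)
    expect_equal(ang, 109.4712206, tolerance = 1e-4)
  }
})

test_that("carbons with aberrant neighbour counts fail individually", {
  at <- data.frame(
    eleno = 1:7,
    elety = c("C1", "O5", "C2", "O1", "C3", "O3", "C4"),
    resid = "MAN", chain = "A", resno = 1, insert = "",
    x = c(0, 1.4, -1.4, 0, 10, 11.4, 8.6),
    y = c(0, 0, 0, 1.4, 0, 0.4, 0.4),
    z = 0, o = 1, b = 0,
    elesy = c("C", "O", "C", "O", "C", "O", "C"),
    stringsAsFactors = FALSE)
  fake <- structure(list(residue_key = "A:1:", atoms = at,
                         sugar_class = "Man"), class = "sugar_residue")
  hs <- place_ring_hydrogens(fake)
  # C1 has 3 neighbours (ok), C3 has 2 (ok, planar-bisector H), C2/C4/C5
  # have too few
  expect_true("C1" %in% hs$parent_atom)
  expect_true(length(attr(hs, "errors")) >= 1)
})

test_that("proton distances discriminate folded from extended builds", {
  back <- build_and_scan(build_spec(
    biantennary_spec(a16 = c(70, 90, 60), bisected = TRUE)))
  pd_b <- proton_distances(back$motif)
  expect_equal(nrow(pd_b), 2)
  expect_true(all(pd_b$noe_compatible))
  expect_true(all(pd_b$distance < 5))

  ext <- build_and_scan(build_spec(
    biantennary_spec(a16 = c(70, 180, 180), bisected = TRUE)))
  pd_e <- proton_distances(ext$motif)
  expect_false(any(pd_e$noe_compatible))
  expect_true(all(pd_e$distance > 5))

  # a proton against itself is 0 and compatible
  self <- proton_distances(back$motif, pairs = list(
    list(a = c(role = "man3", h = "H1"), b = c(role = "man3", h = "H1"))))
  expect_equal(self$distance, 0)
  expect_true(self$noe_compatible)

  # unknown roles fail per pair, not globally
  mixed <- proton_distances(back$motif, pairs = list(
    list(a = c(role = "man3", h = "H1"), b = c(role = "nope", h = "H1")),
    list(a = c(role = "man3", h = "H1"), b = c(role = "man4p", h = "H2"))))
  expect_true(is.na(mixed$distance[1]))
  expect_true(is.finite(mixed$distance[2]))
  expect_length(attr(mixed, "errors"), 1)
})

test_that("hydrogen bonds obey distance, exclusion and symmetry rules", {
  b <- build_glycan(biantennary_spec(a16 = c(70, 90, 60), bisected = TRUE))
  hb <- detect_hbonds(b$atoms)
  # no covalently bonded or 1-3 pair slips through
  expect_true(all(hb$heavy_distance <= 3.5))
  expect_true(all(hb$heavy_distance > 1.8))  # nothing covalent slips through
  # donors are hydroxyl oxygens or amide nitrogens only
  expect_true(all(grepl("^O[12346]$|^N2$", hb$donor_atom)))
  # rigid-motion invariance of the bond list
  moved <- b$atoms
  xyz <- random_rigid_transform(b$atoms[, c("x", "y", "z")], seed = 9)
  moved$x <- xyz[, 1]; moved$y <- xyz[, 2]; moved$z <- xyz[, 3]
  hb2 <- detect_hbonds(moved)
  key <- function(h) sort(paste(h$donor_key, h$donor_atom, h$acceptor_key,
                                h$acceptor_atom))
  expect_equal(key(hb2), key(hb))
  # far-apart residues contribute no cross-residue bonds
  two <- b$atoms[b$atoms$resno %in% c(1), , drop = FALSE]
  far <- b$atoms[b$atoms$resno %in% c(3), , drop = FALSE]
  far$x <- far$x + 50
  both <- detect_hbonds(rbind(two, far))
  expect_equal(nrow(both),
               nrow(detect_hbonds(two)) + nrow(detect_hbonds(far)))
  expect_true(all(both$donor_key == both$acceptor_key))
})

test_that("clash detection honours radii, tolerance and exclusions", {
  # two isolated oxygens exactly at the vdW sum: not a clash; closer than
  # sum - tolerance: reported with positive overlap
  mk <- function(d) data.frame(
    eleno = 1:2, elety = c("O1", "O1"), resid = "HOH", chain = "A",
    resno = 1:2, insert = "", x = c(0, d), y = 0, z = 0, o = 1, b = 0,
    elesy = "O", stringsAsFactors = FALSE)
  expect_equal(nrow(detect_clashes(mk(3.04))), 0)      # r_O + r_O = 3.04
  expect_equal(nrow(detect_clashes(mk(2.70))), 0)      # within tolerance
  cl <- detect_clashes(mk(2.50))
  expect_equal(nrow(cl), 1)
  expect_equal(cl$overlap, 3.04 - 0.4 - 2.50, tolerance = 1e-9)
  expect_error(detect_clashes(data.frame(
    eleno = 1, elety = "XX1", resid = "UNK", chain = "A", resno = 1,
    insert = "", x = 0, y = 0, z = 0, o = 1, b = 0, elesy = "Xx",
    stringsAsFactors = FALSE)), "van der Waals")
})

test_that("bisected extend-a clashes at Man-4'/GlcNAc-7 while back-fold does not", {
  res_a <- build_and_scan(build_spec(
    biantennary_spec(a16 = c(70, 180, 60), bisected = TRUE)))
  roles_a <- res_a$motif$roles
  cl_a <- detect_clashes(glycanfold:::all_graph_atoms(res_a$motif$graph))
  expect_gt(nrow(glycanfold:::clashes_between(cl_a, roles_a$man4p,
                                              roles_a$glcnac7)), 0)

  res_b <- build_and_scan(build_spec(
    biantennary_spec(a16 = c(70, 90, 60), bisected = TRUE)))
  roles_b <- res_b$motif$roles
  cl_b <- detect_clashes(glycanfold:::all_graph_atoms(res_b$motif$graph))
  expect_equal(nrow(glycanfold:::clashes_between(cl_b, roles_b$man4p,
                                                 roles_b$glcnac7)), 0)
})

test_that("superposition recovers exact and noisy transforms", {
  set.seed(21)
  X <- matrix(stats::rnorm(36), 12, 3)
  # identity
  s0 <- superpose(X, X)
  expect_equal(s0$rmsd, 0, tolerance = 1e-12)
  expect_equal(s0$rotation, diag(3), tolerance = 1e-9)
  # known rotation + translation, exact recovery
  R <- glycanfold:::rotation_about_axis(c(2, -1, 0.5), 72)
  Y <- sweep(X %*% t(R), 2, c(4, -3, 9), "+")
  s1 <- superpose(X, Y)
  expect_lt(s1$rmsd, 1e-9)
  expect_equal(s1$rotation, R, tolerance = 1e-9)
  expect_equal(max(abs(glycanfold:::apply_superposition(X, s1) - Y)), 0,
               tolerance = 1e-9)
  # orthonormal proper rotation always
  expect_equal(t(s1$rotation) %*% s1$rotation, diag(3), tolerance = 1e-9)
  expect_equal(det(s1$rotation), 1, tolerance = 1e-9)
  # noisy copy: rmsd matches an independent optimisation oracle
  Z <- Y + matrix(stats::rnorm(36, sd = 0.1), 12, 3)
  s2 <- superpose(X, Z)
  expect_equal(s2$rmsd, oracle_min_rmsd(X, Z), tolerance = 1e-3)
  # rigid-motion invariance of the rmsd
  Xm <- random_rigid_transform(X, seed = 33)
  expect_equal(superpose(Xm, Z)$rmsd, s2$rmsd, tolerance = 1e-9)
  # degeneracies
  expect_error(superpose(X[1:2, ], Y[1:2, ]), "degenerate")
  line <- cbind(1:5, 2 * (1:5), -1 * (1:5))
  expect_error(superpose(line, line), "degenerate")
})

test_that("model extension grafts the chitobiose stem onto a truncated glycan", {
  full_spec <- biantennary_spec(a16 = c(70, 90, 60), bisected = TRUE,
                                chitobiose = TRUE)
  trunc_spec <- biantennary_spec(a16 = c(70, 90, 60), bisected = TRUE,
                                 chitobiose = FALSE)
  # make the truncated core alpha->beta consistent with the donor so shared
  # rings superpose exactly
  full <- build_and_scan(build_spec(full_spec))
  trunc <- build_and_scan(build_spec(trunc_spec))
  ext <- model_extension(trunc$motif, full$motif)
  expect_length(ext$grafted_keys, 2)
  expect_lt(ext$superposition$rmsd, 0.2)
  # grafting a structure onto an identical copy keeps donor atoms in place
  full2 <- build_and_scan(build_spec(full_spec))
  ext2 <- model_extension(full2$motif, full$motif)
  expect_equal(length(ext2$grafted_keys), 0)
  expect_lt(ext2$superposition$rmsd, 1e-9)
  # degenerate: no shared roles
  expect_error(model_extension(trunc$motif, full$motif,
                               shared_roles = character(0)), "degenerate")
  # grafted chitobiose lands where the donor's chitobiose is (same topology)
  g_at <- ext$atoms[ext$atoms$chain != "A", , drop = FALSE]
  expect_gt(nrow(g_at), 20)
  env <- glycanfold:::all_graph_atoms(trunc$motif$graph)
  ext3 <- model_extension(trunc$motif, full$motif, environment = env)
  expect_true(!is.null(ext3$environment_clashes))
})
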