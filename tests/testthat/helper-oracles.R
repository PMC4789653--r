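# Independent oracles and fixture helpers used across the test files.

ocross <- function(a, b) c(a[2] * b[3] - a[3] * b[2],
                           a[3] * b[1] - a[1] * b[3],
                           a[1] * b[2] - a[2] * b[1])

# torsion by explicit frame construction: project the outer bonds onto the
# plane perpendicular to the central bond and take the signed angle between
# the projections (independent of the cross-product formula in the package)
oracle_dihedral <- function(p1, p2, p3, p4) {
  z <- (p3 - p2) / sqrt(sum((p3 - p2)^2))
  proj <- function(v) v - sum(v * z) * z
  u <- proj(p1 - p2)
  w <- proj(p4 - p3)
  ang <- atan2(sum(ocross(u, w) * z), sum(u * w)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

# toroidal distance by explicit scan over all 27 wrap combinations
oracle_toroidal <- function(a, b) {
  best <- Inf
  for (k1 in -1:1) for (k2 in -1:1) for (k3 in -1:1) {
    d <- (a - b) + 360 * c(k1, k2, k3)
    best <- min(best, sqrt(sum(d^2)))
  }
  best
}

# brute-force nearest-reference classification using oracle_toroidal
oracle_classify <- function(triple, cutoff = 45) {
  refs <- reference_conformers()
  d <- vapply(seq_len(nrow(refs)), function(i)
    oracle_toroidal(triple, c(refs$phi[i], refs$psi[i], refs$omega[i])),
    numeric(1))
  i <- which.min(d)  # first minimum = fixed reference order
  list(label = if (d[i] <= cutoff) refs$name[i] else "unclassified",
       distance = d[i])
}

# minimal rmsd under rigid motion by direct optimisation over axis-angle
# parameters (independent of the SVD route)
oracle_min_rmsd <- function(mobile, target) {
  A <- sweep(mobile, 2, colMeans(mobile))
  B <- sweep(target, 2, colMeans(target))
  rot <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    u <- v / th
    ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
                 3, 3, byrow = TRUE)
    cos(th) * diag(3) + sin(th) * ux + (1 - cos(th)) * (u %o% u)
  }
  f <- function(v) sqrt(mean(rowSums((A %*% t(rot(v)) - B)^2)))
  best <- Inf
  for (s in list(c(0, 0, 0), c(pi / 2, 0, 0), c(0, pi / 2, 0),
                 c(0, 0, pi / 2), c(pi, 0, 0), c(0, pi, 0), c(0, 0, pi),
                 c(1.5, 1.5, 1.5))) {
    o <- stats::optim(s, f, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000))
    best <- min(best, o$value)
  }
  best
}

random_rigid_transform <- function(xyz, seed) {
  set.seed(seed)
  v <- stats::rnorm(3)
  R <- glycanfold:::rotation_about_axis(stats::rnorm(3), stats::runif(1, 0, 360))
  sweep(as.matrix(xyz) %*% t(R), 2, v, "+")
}

runif_angle <- function(n) stats::runif(n, -180 + 1e-6, 180)

# TRUE when glycosidic connectivity of a built glycan is geometrically
# decodable: every anomeric carbon sees exactly its true bridge oxygen
# within the covalent cutoff. Uniform random torsions occasionally
# interpenetrate residues so badly that a foreign oxygen sits at bonding
# distance of a C1; connectivity inference from geometry alone is then
# ill-posed for any method, and such conformers are excluded from
# round-trip properties.
decodable_build <- function(b, cutoff = 1.8) {
  at <- b$atoms
  link_o <- c(`2` = "O2", `3` = "O3", `4` = "O4", `6` = "O6")
  for (i in seq_len(nrow(b$nodes))) {
    c1 <- at[at$resno == i & at$elety == "C1", c("x", "y", "z")]
    c1 <- as.numeric(c1)
    parent <- b$nodes$parent_resno[i]
    expect_key <- if (is.na(parent)) NULL else
      c(parent, link_o[[as.character(b$nodes$position[i])]])
    near <- at[at$resno != i &
                 at$elety %in% c("O1", "O2", "O3", "O4", "O6"), ]
    d <- sqrt((near$x - c1[1])^2 + (near$y - c1[2])^2 + (near$z - c1[3])^2)
    hit <- near[d <= cutoff, , drop = FALSE]
    ok <- if (is.null(expect_key)) nrow(hit) == 0 else
      nrow(hit) == 1 && hit$resno == expect_key[1] &&
        hit$elety == expect_key[2]
    if (!ok) return(FALSE)
  }
  TRUE
}

# a random biantennary build specification with known torsions, redrawn
# until the built conformer's connectivity is decodable
random_biantennary <- function(bisected = NULL) {
  for (attempt in 1:50) {
    bis <- if (is.null(bisected)) stats::runif(1) < 0.5 else bisected
    tors <- list(a16 = runif_angle(3), a13 = runif_angle(2),
                 b12 = runif_angle(2), b14 = runif_angle(2))
    spec <- biantennary_spec(a16 = tors$a16, a13 = tors$a13,
                             bisected = bis, b12 = tors$b12,
                             b14 = tors$b14)
    if (decodable_build(build_glycan(spec)))
      return(list(spec = spec, torsions = tors, bisected = bis))
  }
  stop("could not draw a decodable random conformer in 50 attempts")
}

scan_one <- function(path) {
  res <- scan_structure(path)
  expect_length(res, 1)
  res[[1]]
}

build_and_scan <- function(spec, format = c("pdb", "cif")) {
  format <- match.arg(format)
  f <- tempfile(fileext = paste0(".", format))
  on.exit(unlink(f))
  if (format == "pdb") emit_pdb(build_glycan(spec), f)
  else emit_mmcif(build_glycan(spec), f)
  suppressWarnings(scan_one(f))
}
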