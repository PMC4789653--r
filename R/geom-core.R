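# Elementary 3D geometry used throughout: vectors are length-3 numerics,
# coordinate sets are n x 3 matrices in Angstrom.

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

#' Wrap angles into (-180, 180]
#'
#' @param x numeric vector of angles in degrees.
#' @return angles reduced modulo 360 into the half-open interval (-180, 180].
#' @export
wrap_angle <- function(x) {
  w <- x %% 360
  w[w > 180] <- w[w > 180] - 360
  # map -180 to +180 so the interval is half-open on the left
  w[w == -180] <- 180
  w
}

#' Torsion angle of four points
#'
#' Computes the dihedral angle p1-p2-p3-p4 in degrees under the IUPAC sign
#' convention: looking from p2 towards p3, a clockwise rotation of the far
#' bond relative to the near bond is positive. Eclipsed (cis) is 0 and
#' antiperiplanar (trans) is 180.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinate vectors (Angstrom).
#' @return angle in degrees in (-180, 180].
#' @examples
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0))   # 0 (cis)
#' dihedral(c(1, 0, 0), c(0, 0, 0), c(0, 1, 0), c(-1, 1, 0))  # 180 (trans)
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9)
    stop("undefined torsion: consecutive points coincide")
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9)
    stop("undefined torsion: three consecutive points are collinear")
  y <- sum(vcross(n1, n2) * unitv(b2))
  x <- sum(n1 * n2)
  wrap_angle(atan2(y, x) * 180 / pi)
}

bond_angle <- function(p1, p2, p3) {
  u <- unitv(p1 - p2)
  v <- unitv(p3 - p2)
  acos(min(1, max(-1, sum(u * v)))) * 180 / pi
}

# Place a fourth atom from three reference atoms by internal coordinates
# (natural extension reference frame): the new atom is bonded to p3 with the
# given bond length, makes angle p2-p3-new of `ang` degrees, and torsion
# p1-p2-p3-new of `tor` degrees.
place_atom <- function(p1, p2, p3, bond, ang, tor) {
  ang <- ang * pi / 180
  tor <- tor * pi / 180
  bc <- unitv(p3 - p2)
  n <- unitv(vcross(p2 - p1, bc))
  m <- vcross(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  p3 + d[1] * bc + d[2] * m + d[3] * n
}

# Rotation matrix for a right-handed rotation of `theta` degrees about unit
# axis `axis` (Rodrigues form).
rotation_about_axis <- function(axis, theta) {
  u <- unitv(axis)
  th <- theta * pi / 180
  ct <- cos(th)
  st <- sin(th)
  ux <- matrix(c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
               3, 3, byrow = TRUE)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

# Rotation taking unit vector a onto unit vector b.
rotation_between <- function(a, b) {
  a <- unitv(a)
  b <- unitv(b)
  v <- vcross(a, b)
  s <- vnorm(v)
  c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 about any axis perpendicular to a
    perp <- vcross(a, if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0))
    return(rotation_about_axis(perp, 180))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

# The two remaining tetrahedral substituent directions at `center` whose
# existing neighbours are n1 and n2. Returned unit vectors make ~109.47
# degrees with each existing bond; d1 is on the +(u1 x u2) side.
tetrahedral_directions <- function(center, n1, n2) {
  u1 <- unitv(n1 - center)
  u2 <- unitv(n2 - center)
  s <- unitv(-(u1 + u2))
  t <- unitv(vcross(u1, u2))
  target <- cos(109.47 * pi / 180)
  g <- function(h) sum((s * cos(h) + t * sin(h)) * u1) - target
  # g is monotone on [0, pi/2] for any non-degenerate pair
  h <- stats::uniroot(g, c(0, pi / 2), tol = 1e-12)$root
  list(d1 = s * cos(h) + t * sin(h), d2 = s * cos(h) - t * sin(h))
}

#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation and translation minimising the RMSD between
#' paired atom sets, by singular value decomposition of the covariance
#' matrix with a determinant correction that excludes reflections.
#'
#' @param mobile n x 3 matrix of coordinates to move.
#' @param target n x 3 matrix of reference coordinates, row-paired with
#'   `mobile`.
#' @return object of class `"superposition"`: list with `rotation` (3 x 3,
#'   det = +1), `translation` (length 3), `rmsd` (Angstrom) and `n` (number
#'   of pairs). Transformed mobile coordinates are
#'   `mobile %*% t(rotation) + translation` (rowwise).
#' @export
superpose <- function(mobile, target) {
  mobile <- as.matrix(mobile)
  target <- as.matrix(target)
  if (!all(dim(mobile) == dim(target)) || ncol(mobile) != 3)
    stop("mobile and target must be equally sized n x 3 matrices")
  n <- nrow(mobile)
  if (n < 3) stop("superposition is degenerate: need at least 3 atom pairs")
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  A <- sweep(mobile, 2, cm)
  B <- sweep(target, 2, ct)
  if (min(svd(A)$d) < 1e-8 * max(svd(A)$d))
    stop("superposition is degenerate: fitting atoms are collinear")
  H <- t(A) %*% B
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  moved <- A %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - B)^2)))
  structure(list(rotation = R,
                 translation = as.numeric(ct - R %*% cm),
                 rmsd = rmsd, n = n),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("Rigid-body superposition over %d atom pairs, rmsd %.4f A\n",
              x$n, x$rmsd))
  invisible(x)
}

apply_superposition <- function(xyz, sp) {
  sweep(as.matrix(xyz) %*% t(sp$rotation), 2, sp$translation, "+")
}
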