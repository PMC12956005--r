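# Small 3-vector geometry kernel shared by the mutator, hydrogen placement,
# H-bond detection and the fixture generators. All angles in degrees,
# all distances in Angstrom.

.deg2rad <- pi / 180
.rad2deg <- 180 / pi

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

#' Angle at the middle point of three positions
#'
#' @param p1,p2,p3 numeric 3-vectors; the angle is measured at `p2`.
#' @return angle in degrees in \[0, 180\].
#' @keywords internal
pointAngle <- function(p1, p2, p3) {
  u <- unitv(p1 - p2)
  v <- unitv(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) * .rad2deg
}

#' Dihedral angle of four positions
#'
#' Signed torsion p1-p2-p3-p4 about the p2-p3 axis, degrees in (-180, 180].
#' @keywords internal
pointDihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unitv(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- atan2(y, x) * .rad2deg
  if (ang <= -180) ang + 360 else ang
}

#' Place an atom from internal coordinates (NeRF construction)
#'
#' Given three placed atoms a-b-c, returns the position d such that
#' |c-d| = `length`, angle(b, c, d) = `angle` and dihedral(a, b, c, d) =
#' `torsion`.
#'
#' @param a,b,c numeric 3-vectors of already-placed positions.
#' @param length bond length c-d in Angstrom.
#' @param angle bond angle b-c-d in degrees.
#' @param torsion dihedral a-b-c-d in degrees.
#' @return numeric 3-vector.
#' @keywords internal
placeAtom <- function(a, b, c, length, angle, torsion) {
  bc <- unitv(c - b)
  n <- vcross(b - a, bc)
  if (vnorm(n) < 1e-10) {
    # a,b,c collinear: pick an arbitrary perpendicular reference
    ref <- if (abs(bc[1L]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    n <- vcross(ref, bc)
  }
  n <- unitv(n)
  m <- vcross(n, bc)
  ang <- angle * .deg2rad
  tor <- torsion * .deg2rad
  d2 <- c(-length * cos(ang),
          length * sin(ang) * cos(tor),
          length * sin(ang) * sin(tor))
  c + d2[1L] * bc + d2[2L] * m + d2[3L] * n
}

# Rotate points (rows of a matrix) about a unit axis through the origin.
rotateAboutAxis <- function(xyz, axis, angle_deg) {
  k <- unitv(axis)
  th <- angle_deg * .deg2rad
  K <- matrix(c(0, -k[3L], k[2L], k[3L], 0, -k[1L], -k[2L], k[1L], 0),
              3L, 3L, byrow = TRUE)
  R <- diag(3L) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  xyz %*% t(R)
}

# Pairwise distance between two coordinate matrices (n x 3, m x 3).
crossDist <- function(a, b) {
  a <- matrix(a, ncol = 3L)
  b <- matrix(b, ncol = 3L)
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}
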