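#' Torsion angle of four points
#'
#' Computes the dihedral angle defined by four atom positions using the
#' IUPAC convention: the angle is 0 for a cis arrangement and positive for a
#' clockwise rotation of the 3-4 bond relative to the 1-2 bond when viewed
#' from atom 2 towards atom 3. The result lies in (-180, 180] degrees.
#'
#' @param p1,p2,p3,p4 numeric length-3 vectors, Cartesian coordinates in
#'   Angstrom.
#' @return dihedral angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2))
  ang <- atan2(y, x) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates
#'
#' Natural-extension-reference-frame (NeRF) construction: given three
#' previously placed atoms `a`, `b`, `c`, returns the position `d` such that
#' |c-d| = `bond`, the angle b-c-d equals `angle` and the torsion a-b-c-d
#' equals `torsion` (degrees, same sign convention as [dihedral_angle()]).
#'
#' @param a,b,c numeric length-3 coordinate vectors.
#' @param bond bond length c-d in Angstrom.
#' @param angle valence angle b-c-d in degrees.
#' @param torsion dihedral a-b-c-d in degrees.
#' @return length-3 coordinate vector.
#' @export
place_atom <- function(a, b, c, bond, angle, torsion) {
  th <- angle * pi / 180
  ph <- torsion * pi / 180
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(ph), bond * sin(th) * sin(ph))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- cross3(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- cross3(n, bc)
  d <- c + bc * d2[1] + m * d2[2] + n * d2[3]
  d
}

# Random rigid-body transform (rotation + translation) of an n x 3 matrix.
# Used by invariance tests and multimer placement.
rigid_transform <- function(xyz, rotation = NULL, translation = c(0, 0, 0)) {
  if (is.null(rotation)) rotation <- diag(3)
  sweep(xyz %*% t(rotation), 2, translation, "+")
}

# Rotation matrix about the z axis by `theta` radians.
rot_z <- function(theta) {
  ct <- cos(theta); st <- sin(theta)
  matrix(c(ct, -st, 0, st, ct, 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

# Uniform random rotation matrix (for property tests), via QR of a Gaussian.
random_rotation <- function() {
  qr_res <- qr(matrix(stats::rnorm(9), 3, 3))
  q <- qr.Q(qr_res)
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}
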