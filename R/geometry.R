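# Small 3-vector helpers shared by the secondary-structure code and the
# idealized-backbone builders. All coordinates are in Angstroms.

.vnorm <- function(v) sqrt(sum(v * v))

.vunit <- function(v) {
  n <- .vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  v / n
}

.vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place an atom from internal coordinates
#'
#' Standard natural-extension (NeRF) construction: given three reference
#' positions \code{a}, \code{b}, \code{c}, returns the position \code{d}
#' bonded to \code{c} at the stated bond length, with bond angle
#' \code{b-c-d} and proper dihedral \code{a-b-c-d}.
#'
#' @param a,b,c numeric 3-vectors, reference positions.
#' @param bond bond length c-d in Angstroms.
#' @param angle bond angle b-c-d in degrees.
#' @param dihedral proper dihedral a-b-c-d in degrees.
#' @return numeric 3-vector, the placed position.
#' @keywords internal
place_atom <- function(a, b, c, bond, angle, dihedral) {
  ang <- angle * pi / 180
  dih <- dihedral * pi / 180
  bc <- .vunit(c - b)
  n <- .vunit(.vcross(b - a, bc))
  m <- .vcross(n, bc)
  d <- c(-bond * cos(ang),
         bond * sin(ang) * cos(dih),
         -bond * sin(ang) * sin(dih))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Proper dihedral angle of four points, in degrees
#' @param a,b,c,d numeric 3-vectors.
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- .vcross(b1, b2)
  n2 <- .vcross(b2, b3)
  m1 <- .vcross(n1, .vunit(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Rotation matrices about the lab axes (degrees).
.rot_z <- function(theta) {
  t <- theta * pi / 180
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}
.rot_y <- function(theta) {
  t <- theta * pi / 180
  matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
}
.rot_x <- function(theta) {
  t <- theta * pi / 180
  matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, 3, byrow = TRUE)
}
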