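# Small 3-vector helpers used throughout; all coordinates in Angstrom.

vnorm <- function(v) sqrt(sum(v * v))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Euclidean distance between two points
#' @param a,b numeric 3-vectors
#' @return distance in Angstrom
#' @keywords internal
point_dist <- function(a, b) vnorm(a - b)

#' Dihedral angle defined by four points
#'
#' Signed torsion angle a-b-c-d using the IUPAC convention (cis = 0, looking
#' from b to c a clockwise rotation of d is positive).
#'
#' @param a,b,c,d numeric 3-vectors
#' @return angle in degrees in (-180, 180]
#' @keywords internal
dihedral_angle <- function(a, b, c, d) {
  b1 <- b - a
  b2 <- c - b
  b3 <- d - c
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

#' Place an atom from internal coordinates (NeRF)
#'
#' Natural extension reference frame: given three previously placed atoms
#' a-b-c, place d such that |c-d| = `bond`, angle b-c-d = `angle` and torsion
#' a-b-c-d = `torsion`.
#'
#' @param a,b,c numeric 3-vectors, the reference atoms
#' @param bond bond length c-d (Angstrom)
#' @param angle bond angle b-c-d (degrees)
#' @param torsion dihedral a-b-c-d (degrees)
#' @return position of d as a numeric 3-vector
#' @keywords internal
nerf_place <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * pi / 180
  tor <- torsion * pi / 180
  # local displacement in the frame of c
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  bc <- unit(c - b)
  n <- unit(vcross(b - a, bc))
  m <- vcross(n, bc)   # completes right-handed frame (bc, m, n)
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

#' Random rigid motion
#'
#' Draws a uniformly random rotation (via a normalised quaternion) and a
#' translation with components in `trans_range`. Used by the property tests
#' for rigid-motion invariance and by the synthetic generators.
#'
#' @param trans_range numeric length-2, range of each translation component
#' @return list with `R` (3x3 rotation matrix) and `t` (3-vector)
#' @export
random_rigid_motion <- function(trans_range = c(-50, 50)) {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
    nrow = 3, byrow = TRUE)
  t <- stats::runif(3, trans_range[1], trans_range[2])
  list(R = R, t = t)
}

#' Apply a rigid motion to an n x 3 coordinate matrix
#' @param xyz n x 3 matrix
#' @param motion list with rotation `R` and translation `t`
#' @return transformed n x 3 matrix
#' @export
apply_rigid_motion <- function(xyz, motion) {
  xyz <- as.matrix(xyz)
  sweep(xyz %*% t(motion$R), 2, -motion$t)
}

# rotation matrix taking unit vector u onto unit vector v
rotation_between <- function(u, v) {
  u <- unit(u); v <- unit(v)
  c_ <- sum(u * v)
  if (c_ > 1 - 1e-12) return(diag(3))
  if (c_ < -1 + 1e-12) {
    # 180 degrees about any axis perpendicular to u
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(vcross(u, p))
    return(rotation_about_axis(ax, 180))
  }
  ax <- vcross(u, v)
  s <- vnorm(ax)
  K <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + K + K %*% K * ((1 - c_) / s^2)
}

rotation_about_axis <- function(axis, angle_deg) {
  a <- unit(axis)
  th <- angle_deg * pi / 180
  K <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0),
              nrow = 3, byrow = TRUE)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}
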