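# Low-level Cartesian geometry: angles, dihedrals, internal-coordinate atom
# placement (NeRF), axis rotations, Kabsch superposition. All angles at this
# level are in degrees at the interface, radians internally; coordinates in
# Angstrom.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v * v))

vunit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length vector")
  v / n
}

vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Bond angle at b, in degrees
#' @param a,b,c numeric length-3 coordinates
#' @return angle a-b-c in degrees, in [0, 180]
#' @keywords internal
angle_deg <- function(a, b, c) {
  u <- vunit(a - b); v <- vunit(c - b)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

#' Torsion angle a-b-c-d, in degrees
#'
#' Signed dihedral about the b-c axis, IUPAC convention: cis = 0, range
#' (-180, 180].
#' @param a,b,c,d numeric length-3 coordinates
#' @return dihedral in degrees
#' @keywords internal
dihedral_deg <- function(a, b, c, d) {
  b1 <- b - a; b2 <- c - b; b3 <- d - c
  n1 <- vcross(b1, b2); n2 <- vcross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * vunit(b2))
  atan2(y, x) / DEG
}

# Place atom D given reference atoms A-B-C, a bond length C-D, the angle
# B-C-D and the torsion A-B-C-D (degrees). Standard NeRF construction.
place_atom <- function(a, b, c, bond, angle, torsion) {
  ang <- angle * DEG; tor <- torsion * DEG
  bc <- vunit(c - b)
  n <- vunit(vcross(b - a, bc))
  m <- cbind(bc, vcross(n, bc), n)
  d2 <- c(-bond * cos(ang),
          bond * sin(ang) * cos(tor),
          bond * sin(ang) * sin(tor))
  c(c + m %*% d2)
}

# Rotation matrix for rotation by theta degrees about unit axis (Rodrigues).
rotation_about_axis <- function(axis, theta) {
  u <- vunit(axis); t <- theta * DEG
  ct <- cos(t); st <- sin(t)
  ux <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  ct * diag(3) + st * ux + (1 - ct) * (u %o% u)
}

# Rotate rows of xyz (n x 3) by theta degrees about the axis through `origin`
# with direction `axis`.
rotate_points <- function(xyz, origin, axis, theta) {
  R <- rotation_about_axis(axis, theta)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of `mobile` onto `reference` using a proper
#' rotation only (determinant +1; reflections are never returned, so chirality
#' is preserved).
#'
#' @param mobile,reference n x 3 coordinate matrices with matched rows
#' @return list with `rotation` (3 x 3), `translation` (length 3; the
#'   transform is `x %*% t(rotation) + translation`), and `rmsd` in Angstrom
#' @keywords internal
kabsch <- function(mobile, reference) {
  if (!is.matrix(mobile)) mobile <- matrix(mobile, ncol = 3, byrow = TRUE)
  if (!is.matrix(reference)) reference <- matrix(reference, ncol = 3, byrow = TRUE)
  stopifnot(ncol(mobile) == 3, ncol(reference) == 3)
  if (nrow(mobile) != nrow(reference))
    stop("superposition selections have different sizes")
  if (nrow(mobile) < 3) stop("superposition needs at least 3 atoms")
  cm <- colMeans(mobile); cr <- colMeans(reference)
  P <- sweep(mobile, 2, cm); Q <- sweep(reference, 2, cr)
  s <- svd(t(P) %*% Q)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = cr - c(cm %*% t(R)), rmsd = rmsd)
}

# wrap an angle in degrees into [-180, 180)
wrap_angle <- function(x) ((x + 180) %% 360) - 180

# smallest absolute angular difference in degrees
angle_diff <- function(a, b) {
  d <- wrap_angle(a - b)
  abs(d)
}
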