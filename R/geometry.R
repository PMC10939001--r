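# Rigid-body and internal-coordinate geometry primitives.
# Positions are N x 3 matrices in Angstrom; angles at the user level are in
# degrees, internal trigonometry in radians.

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

vnorm <- function(v) sqrt(sum(v * v))
unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize near-zero vector")
  v / n
}

#' Rotation matrix about an arbitrary axis
#'
#' Rodrigues rotation by `theta_deg` degrees about the (unnormalized) `axis`.
#'
#' @param axis length-3 axis vector.
#' @param theta_deg rotation angle in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
rotation_about_axis <- function(axis, theta_deg) {
  u <- unit(axis)
  th <- deg2rad(theta_deg)
  c1 <- cos(th); s1 <- sin(th)
  ux <- u[1]; uy <- u[2]; uz <- u[3]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3, 3, byrow = TRUE)
  diag(3) * c1 + s1 * K + (1 - c1) * (u %o% u)
}

rot_z <- function(theta_deg) rotation_about_axis(c(0, 0, 1), theta_deg)
rot_y <- function(theta_deg) rotation_about_axis(c(0, 1, 0), theta_deg)

#' Euler rotation matrix (z-y-z, surface convention)
#'
#' Returns `Rz(gamma) %*% Ry(beta) %*% Rz(alpha)`: the body is first spun by
#' `alpha` about its z axis, tilted by `beta`, then given its azimuthal
#' orientation `gamma` about the surface normal.  With this ordering a global
#' rotation of the laboratory frame about z adds directly to `gamma`, which is
#' the angle the 3-fold surface-symmetry augmentation shifts by 120 degrees.
#'
#' @param alpha,beta,gamma Euler angles in degrees.
#' @return 3 x 3 rotation matrix.
#' @export
euler_matrix <- function(alpha, beta, gamma) {
  rot_z(gamma) %*% rot_y(beta) %*% rot_z(alpha)
}

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention; result in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 length-3 position vectors.
#' @return dihedral angle in degrees.
#' @export
measure_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- rad2deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

# cross product (kept local; avoids dragging a dependency in for one line)
pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Place a fourth atom from internal coordinates (NeRF)
#'
#' Natural-extension-reference-frame placement: given positions of three
#' consecutive atoms `a`, `b`, `c`, returns the position of atom `d` with bond
#' length `|cd| = bond`, angle b-c-d `angle_deg` and dihedral a-b-c-d
#' `torsion_deg`.
#'
#' @param a,b,c length-3 positions of the three reference atoms.
#' @param bond bond length c-d in Angstrom.
#' @param angle_deg bond angle b-c-d in degrees.
#' @param torsion_deg dihedral a-b-c-d in degrees.
#' @return length-3 position of the new atom.
#' @export
nerf_place <- function(a, b, c, bond, angle_deg, torsion_deg) {
  th <- deg2rad(angle_deg)
  ph <- deg2rad(torsion_deg)
  d_local <- bond * c(-cos(th), sin(th) * cos(ph), -sin(th) * sin(ph))
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  M <- cbind(bc, m, n)
  as.numeric(c + M %*% d_local)
}

#' Optimal superposition of two point sets (Kabsch)
#'
#' Returns the proper rotation `R` and translation that map `P` onto `Q`
#' minimizing the RMSD, together with the minimized RMSD.  Reflections are
#' excluded (determinant of `R` is +1).
#'
#' @param P,Q N x 3 coordinate matrices in matching atom order.
#' @return list with elements `R` (3 x 3), `center_P`, `center_Q`, `rmsd`.
#' @export
kabsch <- function(P, Q) {
  P <- as.matrix(P); Q <- as.matrix(Q)
  stopifnot(nrow(P) == nrow(Q), ncol(P) == 3, ncol(Q) == 3)
  cp <- colMeans(P)
  cq <- colMeans(Q)
  P0 <- sweep(P, 2, cp)
  Q0 <- sweep(Q, 2, cq)
  H <- t(P0) %*% Q0
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  D <- diag(c(1, 1, d))
  R <- sv$v %*% D %*% t(sv$u)
  P1 <- P0 %*% t(R)
  rmsd <- sqrt(mean(rowSums((P1 - Q0)^2)))
  list(R = R, center_P = cp, center_Q = cq, rmsd = rmsd)
}

# Rigid transform mapping the template triple (t1,t2,t3) exactly onto the
# target triple; exact when the two triples are congruent.
frame_transform <- function(t1, t2, t3, u1, u2, u3) {
  P <- rbind(t1, t2, t3)
  Q <- rbind(u1, u2, u3)
  k <- kabsch(P, Q)
  list(R = k$R, shift = k$center_Q, center = k$center_P)
}

apply_frame_transform <- function(tr, X) {
  sweep(sweep(X, 2, tr$center) %*% t(tr$R), 2, tr$shift, "+")
}

# wrap values into [lo, lo + period)
wrap_period <- function(x, lo, period) {
  lo + (x - lo) %% period
}
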