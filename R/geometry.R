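# Internal 3D geometry helpers: internal-coordinate atom placement (NeRF),
# ideal backbone parameters, and rigid-body superposition (Kabsch).

# Ideal backbone geometry (lengths in Angstrom, angles in degrees)
IDEAL_GEOM <- list(
  b_n_ca = 1.46, b_ca_c = 1.52, b_c_n = 1.33, b_c_o = 1.23, b_ca_cb = 1.53,
  a_n_ca_c = 111.0, a_ca_c_n = 117.0, a_c_n_ca = 121.0,
  a_ca_c_o = 120.5, a_c_ca_cb = 110.5, t_n_c_ca_cb = -122.6,
  omega = 180.0,
  phi_psi = list(extended = c(-140, 135), helix = c(-57, -47))
)

deg2rad <- function(d) d * pi / 180

# Place atom D given positions A, B, C, the C-D bond length, the B-C-D
# angle and the A-B-C-D torsion (natural extension reference frame).
place_atom <- function(A, B, C, bond, angle_deg, torsion_deg) {
  theta <- deg2rad(angle_deg)
  chi <- deg2rad(torsion_deg)
  bc <- C - B
  bc <- bc / sqrt(sum(bc^2))
  ab <- B - A
  n <- pracma_cross(ab, bc)
  n <- n / sqrt(sum(n^2))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(theta),
          bond * sin(theta) * cos(chi),
          bond * sin(theta) * sin(chi))
  C + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# Optimal rigid superposition (Kabsch, via SVD): returns rotation R and
# translation t such that R %*% t(x) + t best fits y in least squares.
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), nrow(x) >= 3)
  cx <- unname(colMeans(x))
  cy <- unname(colMeans(y))
  xc <- sweep(x, 2, cx)
  yc <- sweep(y, 2, cy)
  h <- t(xc) %*% yc
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  rot <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  trans <- cy - as.vector(rot %*% cx)
  fitted <- sweep(x %*% t(rot), 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((fitted - y)^2)))
  list(rotation = rot, translation = trans, rmsd = rmsd)
}

apply_transform <- function(xyz, transform) {
  sweep(xyz %*% t(transform$rotation), 2, transform$translation, "+")
}

rigid_transform_structure <- function(s, transform) {
  xyz <- apply_transform(atom_xyz(s$atoms), transform)
  s$atoms$x <- xyz[, 1]
  s$atoms$y <- xyz[, 2]
  s$atoms$z <- xyz[, 3]
  s
}

# Rotation matrix mapping unit vector a onto unit vector b (Rodrigues).
rotation_to <- function(a, b) {
  a <- a / sqrt(sum(a^2)); b <- b / sqrt(sum(b^2))
  v <- pracma_cross(a, b)
  s <- sqrt(sum(v^2)); c_ <- sum(a * b)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any perpendicular axis
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- pracma_cross(a, p); v <- v / sqrt(sum(v^2))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0),
               3, 3, byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c_) / s^2)
}

rotation_about_z <- function(deg) {
  th <- deg2rad(deg)
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         3, 3, byrow = TRUE)
}
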