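# Small vector-geometry kernel shared by all modules. Internal unit is
# Angstrom throughout; user-facing observables convert to nm at the edge.

NM_PER_ANGSTROM <- 0.1

vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

vnorm <- function(a) sqrt(sum(a * a))

vunit <- function(a) {
  n <- vnorm(a)
  if (n < 1e-12) stop("cannot normalize a zero-length vector")
  a / n
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking down the p2->p3 bond, a clockwise rotation
#' of p4 relative to p1 is positive. Returns degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 numeric 3-vectors (Angstrom; any consistent unit).
#' @return signed dihedral in degrees.
#' @keywords internal
dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  m1 <- vcross(n1, b2 / vnorm(b2))
  rad2deg(atan2(sum(m1 * n2), sum(n1 * n2)))
}

# Rotation matrix for rotation by `angle_deg` about unit axis `u`
# (Rodrigues form).
rotation_matrix <- function(u, angle_deg) {
  u <- vunit(u)
  th <- deg2rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  ux <- u[1L]; uy <- u[2L]; uz <- u[3L]
  K <- matrix(c(0, -uz, uy, uz, 0, -ux, -uy, ux, 0), 3L, 3L, byrow = TRUE)
  diag(3L) * ct + st * K + (1 - ct) * tcrossprod(u)
}

# Rotate rows of xyz (n x 3) about the axis through `origin` with direction
# `axis` by `angle_deg`.
rotate_about_axis <- function(xyz, origin, axis, angle_deg) {
  R <- rotation_matrix(axis, angle_deg)
  sweep(sweep(xyz, 2L, origin) %*% t(R), 2L, origin, `+`)
}

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the rotation + translation minimizing the RMSD of `mobile` onto
#' `target` (both n x 3, matched rows).
#'
#' @return list with `R` (3x3 rotation), `t` (translation), `xyz` (superposed
#'   mobile coordinates) and `rmsd` (Angstrom).
#' @keywords internal
kabsch <- function(mobile, target) {
  stopifnot(nrow(mobile) == nrow(target))
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  A <- sweep(mobile, 2L, cm)
  B <- sweep(target, 2L, ct)
  H <- crossprod(A, B)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  xyz <- A %*% t(R)
  xyz <- sweep(xyz, 2L, ct, `+`)
  list(R = R, t = ct - as.vector(R %*% cm), xyz = xyz,
       rmsd = sqrt(mean(rowSums((xyz - target)^2))))
}

raw_rmsd <- function(a, b) sqrt(mean(rowSums((a - b)^2)))

# Best-fit plane through points (n x 3): returns unit normal and centroid.
# Normal is the eigenvector of the covariance with smallest eigenvalue.
fit_plane <- function(xyz) {
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2L, ctr)
  e <- eigen(crossprod(X) / nrow(X), symmetric = TRUE)
  n <- e$vectors[, 3L]
  list(normal = vunit(n), center = ctr)
}

# Deterministic unit sphere point set (golden-spiral / Fibonacci lattice).
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(cos(theta) * sin(phi), sin(theta) * sin(phi), cos(phi))
}
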