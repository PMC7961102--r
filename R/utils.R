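# Internal helpers: typed error conditions and small geometry primitives.

.cf_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "cofilactin_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

stop_config     <- function(msg) .cf_stop(msg, "cofilactin_config_error")
stop_structural <- function(msg) .cf_stop(msg, "cofilactin_structural_error")
stop_topology   <- function(msg) .cf_stop(msg, "cofilactin_topology_error")
stop_input      <- function(msg) .cf_stop(msg, "cofilactin_input_error")
stop_format     <- function(msg) .cf_stop(msg, "cofilactin_format_error")
stop_domain     <- function(msg) .cf_stop(msg, "cofilactin_domain_error")
stop_generation <- function(msg) .cf_stop(msg, "cofilactin_generation_error")
stop_numerical  <- function(msg) .cf_stop(msg, "cofilactin_numerical_error")

`%||%` <- function(a, b) if (is.null(a)) b else a

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

## Rotation matrix (column-vector convention) about z by `deg` degrees.
rot_z <- function(deg) {
  a <- deg2rad(deg)
  matrix(c(cos(a), sin(a), 0,
           -sin(a), cos(a), 0,
           0, 0, 1), 3, 3)
}

## Rotation about an arbitrary unit axis through the origin (Rodrigues).
rot_axis <- function(axis, deg) {
  u <- axis / sqrt(sum(axis^2))
  a <- deg2rad(deg)
  K <- matrix(c(0, u[3], -u[2],
                -u[3], 0, u[1],
                u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

## Rotate rows of xyz about an axis through `origin`.
rotate_about <- function(xyz, origin, axis, deg) {
  R <- rot_axis(axis, deg)
  sweep(sweep(xyz, 2, origin) %*% t(R), 2, origin, `+`)
}

vnorm <- function(v) sqrt(sum(v^2))
unit <- function(v) v / vnorm(v)
vcross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

## Signed dihedral (IUPAC convention) of four points, degrees in (-180, 180].
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- vcross(b1, b2)
  n2 <- vcross(b2, b3)
  x <- sum(n1 * n2)
  y <- sum(vcross(n1, n2) * unit(b2))
  rad2deg(atan2(y, x))
}

## Rotation angle of a proper rotation matrix, degrees in [0, 180].
rotation_angle <- function(R) {
  tr <- sum(diag(R))
  rad2deg(acos(min(1, max(-1, (tr - 1) / 2))))
}

## Squared cross distances between two coordinate matrices (na x 3, nb x 3).
cross_dist2 <- function(a, b) {
  a2 <- rowSums(a^2)
  b2 <- rowSums(b^2)
  outer(a2, b2, `+`) - 2 * tcrossprod(a, b)
}

## Count pairs strictly closer than cutoff (Angstrom).
count_within <- function(a, b, cutoff) {
  sum(cross_dist2(a, b) < cutoff^2)
}

## Draw a seeded Gaussian cluster of n points whose mean is exactly `center`.
gauss_cluster <- function(n, center, sd) {
  pts <- matrix(stats::rnorm(3L * n, sd = sd), ncol = 3)
  pts <- sweep(pts, 2, colMeans(pts))
  sweep(pts, 2, center, `+`)
}
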