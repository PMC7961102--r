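# Independent oracles and fixture builders used across the suite.

## Horn's quaternion-based absolute-orientation solution: an independent
## route to the optimal superposition RMSD, used to cross-check the
## SVD-based Kabsch implementation.
quaternion_rmsd <- function(mobile, reference) {
  X <- sweep(mobile, 2, colMeans(mobile))
  Y <- sweep(reference, 2, colMeans(reference))
  M <- crossprod(X, Y)
  Sxx <- M[1, 1]; Sxy <- M[1, 2]; Sxz <- M[1, 3]
  Syx <- M[2, 1]; Syy <- M[2, 2]; Syz <- M[2, 3]
  Szx <- M[3, 1]; Szy <- M[3, 2]; Szz <- M[3, 3]
  N <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz
  ), 4, 4, byrow = TRUE)
  ev <- eigen(N, symmetric = TRUE)
  q <- ev$vectors[, 1]
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  R <- matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), 3, 3, byrow = TRUE)
  sqrt(mean(rowSums((X %*% t(R) - Y)^2)))
}

## O(N^2) double-loop contact counter (strict inequality at the cutoff).
brute_force_contacts <- function(a, b, cutoff) {
  n <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(b))) {
      if (sqrt(sum((a[i, ] - b[j, ])^2)) < cutoff) n <- n + 1L
    }
  }
  n
}

## Apply one global rigid motion to every frame of a filament system.
transform_system <- function(system, R, t_vec) {
  move <- function(xyz) {
    for (f in seq_len(dim(xyz)[3])) {
      xyz[, , f] <- sweep(xyz[, , f, drop = TRUE] %*% t(R), 2, t_vec, `+`)
    }
    xyz
  }
  system$subunits <- lapply(system$subunits, function(s) {
    s$xyz <- move(s$xyz); s
  })
  system$occupancy <- lapply(system$occupancy, function(r) {
    r$xyz <- move(r$xyz); r
  })
  system
}

## Arbitrary (seeded) proper rotation matrix.
random_rotation <- function(seed) {
  set.seed(seed)
  ax <- rnorm(3)
  rot_about_axis <- function(axis, deg) {
    u <- axis / sqrt(sum(axis^2))
    a <- deg * pi / 180
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
  }
  rot_about_axis(ax, runif(1, 10, 170))
}

## Small random "subunit" system: two actin-kind subunits with fully random
## coordinates, for contact-oracle checks.
random_pair_system <- function(seed, n_res = 60L) {
  set.seed(seed)
  sel <- residue_selections(
    dloop = 5:8,
    target_cleft = 21:24,
    subdomains = list(sd1 = 1:4, sd2 = 5:20, sd3 = 21:40,
                      sd4 = 41:n_res)
  )
  mk <- function() {
    subunit_template(matrix(runif(n_res * 3, 0, 30), ncol = 3),
                     kind = "actin", selections = sel)
  }
  t1 <- mk(); t2 <- mk()
  filament_system(list(
    cofilactin:::make_subunit_entry(1L, t1, t1$ca_coords),
    cofilactin:::make_subunit_entry(2L, t2, t2$ca_coords)
  ))
}

table1_rows <- function() {
  list(
    slow_twist = transition_params(165.1, 155.1, 1.4, 1.1),
    fast_twist = transition_params(150.0, 169.4, 0.1, 2.9),
    slow_phi   = transition_params(-9.0, -28.9, -0.3, 1.1),
    fast_phi   = transition_params(-29.4, -4.2, 2.2, 2.8)
  )
}
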