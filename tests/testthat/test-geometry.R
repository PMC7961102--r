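test_that("twist estimator recovers prescribed twists across a grid", {
  tpl <- bare_actin_template()
  for (twist in c(155, 160, 162, 167, 170)) {
    sys <- make_filament(tpl, n_subunits = 5,
                         helical = helical_params(twist))
    tw <- twist_profile(sys)
    expect_true(all(abs(tw$mean - twist) < 1e-6))
  }
})

test_that("twist of an untransformed or known-rotation pair is exact", {
  tpl <- bare_actin_template()
  ## Two identical, untransformed subunits: zero rotation. Build by hand so
  ## no helical transform is applied.
  entry <- function(p) cofilactin:::make_subunit_entry(p, tpl,
                                                       tpl$ca_coords)
  flat <- filament_system(list(entry(1L), entry(2L)))
  expect_lt(twist_profile(flat)$mean[1], 1e-8)
  ## Pair related by a known rotation about the axis returns that angle.
  for (alpha in c(10, 90, 179)) {
    sys <- make_filament(tpl, n_subunits = 2,
                         helical = helical_params(alpha))
    expect_lt(abs(twist_profile(sys)$mean[1] - alpha), 1e-6)
  }
})

test_that("azimuthal estimator approximates the screw estimator on ideal helices", {
  ## The azimuthal projection fits the filament axis from the finite set of
  ## subunit centers, so individual pairs wobble; its average should still
  ## track the generating twist closely.
  sys <- make_filament(bare_actin_template(), n_subunits = 12,
                       helical = helical_params(167))
  tw <- twist_profile(sys, method = "azimuth")
  expect_lt(abs(mean(tw$mean) - 167), 1)
  expect_true(all(abs(tw$mean - 167) < 12))
})

test_that("flatness dihedral is chirality-sensitive and the cleft distance is not", {
  sys <- make_filament(make_subunit_template(-20, 25, seed = 3),
                       n_subunits = 1)
  g <- flatness_and_cleft(sys, 1, 1)
  ## Mirror image: negate x on all coordinates.
  mirror <- sys
  mirror$subunits[[1]]$xyz[, 1, ] <- -mirror$subunits[[1]]$xyz[, 1, ]
  gm <- flatness_and_cleft(mirror, 1, 1)
  expect_equal(gm$phi, -g$phi, tolerance = 1e-9)
  expect_equal(gm$d, g$d, tolerance = 1e-12)
  ## Four coplanar subdomain centers give phi = 0.
  planar <- make_filament(make_subunit_template(0, 25, seed = 4),
                          n_subunits = 1)
  expect_lt(abs(flatness_and_cleft(planar, 1, 1)$phi), 1e-6)
  ## Cofilin subunits have no flatness.
  cof <- make_cofilactin_filament(11)
  expect_error(flatness_and_cleft(
    filament_system(list(cofilactin:::make_subunit_entry(
      1L, cofilin_template(), cofilin_template()$ca_coords))), 1, 1),
    class = "cofilactin_domain_error")
})

test_that("contact counts equal the brute-force oracle on random systems", {
  spec <- contact_spec("all", "all", cutoff = 10)
  for (s in 1:50) {
    sys <- random_pair_system(s)
    a <- cofilactin:::subunit_coords(sys, 1, 1)
    b <- cofilactin:::subunit_coords(sys, 2, 1)
    expect_identical(contact_count(sys, 1, c(1L, 2L), spec),
                     brute_force_contacts(a, b, 10))
  }
})

test_that("the contact cutoff is a strict inequality", {
  sel <- residue_selections(dloop = 2:3, target_cleft = 4:4,
                            subdomains = list(sd1 = 1L, sd2 = 2:3,
                                              sd3 = 4L, sd4 = 5L))
  mk <- function(x0) subunit_template(
    cbind(c(0, 1, 2, 3, 4) + x0, 0, 0), kind = "actin", selections = sel)
  ta <- mk(0); tb <- mk(14)  # closest inter-subunit pair exactly 10 apart
  sys <- filament_system(list(
    cofilactin:::make_subunit_entry(1L, ta, ta$ca_coords),
    cofilactin:::make_subunit_entry(2L, tb, tb$ca_coords)
  ))
  spec <- contact_spec("all", "all", cutoff = 10)
  expect_identical(contact_count(sys, 1, c(1L, 2L), spec), 0L)
  spec2 <- contact_spec("all", "all", cutoff = 10.001)
  expect_identical(contact_count(sys, 1, c(1L, 2L), spec2), 1L)
})

test_that("D-loop contact profile separates extended from retracted D-loops", {
  bare <- make_bare_filament(8)
  prof <- dloop_contact_profile(bare)
  ## Strictly positive, position-uniform counts for extended D-loops.
  expect_true(all(prof$values > 0))
  expect_identical(length(unique(as.integer(prof$values))), 1L)
  ## Per-position counts equal per-pair contact_count calls.
  for (j in seq_along(prof$positions)) {
    n <- prof$positions[j]
    expect_identical(prof$values[j, 1],
                     contact_count(bare, 1, c(n, n + 2L), prof$spec))
  }
  ## Retracted (cofilactin-like) D-loops: zero contacts at every position.
  cof <- make_filament(cofilactin_actin_template(), n_subunits = 8,
                       helical = helical_params(162))
  expect_true(all(dloop_contact_profile(cof)$values == 0))
})

test_that("interface integrity flags exactly the broken junctions", {
  sys <- make_bare_filament(8)
  ii <- interface_integrity(sys)
  expect_false(any(ii$ruptured))
  ## Translate the pointed half far away: only the two spanning
  ## longitudinal interfaces rupture.
  broken <- sys
  for (p in 5:8) {
    j <- which(positions(broken) == p)
    broken$subunits[[j]]$xyz[, 1, ] <- broken$subunits[[j]]$xyz[, 1, ] + 200
  }
  ii2 <- interface_integrity(broken)
  expect_identical(ii2$barbed[ii2$ruptured], c(3L, 4L))
  ## Counts equal the brute-force oracle.
  for (r in seq_len(nrow(ii))) {
    a <- cofilactin:::subunit_coords(sys, ii$barbed[r], 1)
    b <- cofilactin:::subunit_coords(sys, ii$pointed[r], 1)
    expect_identical(ii$n_contacts[r], brute_force_contacts(a, b, 10))
  }
})

test_that("rmsd series is zero under rigid motion and bounded by point displacements", {
  base <- make_bare_filament(4)
  ## Frames that differ from frame 1 by rigid motion only.
  xyz1 <- lapply(base$subunits, function(s) s$xyz[, , 1, drop = TRUE])
  R <- random_rotation(5)
  rigid <- base
  for (j in seq_along(rigid$subunits)) {
    moved <- sweep(xyz1[[j]] %*% t(R), 2, c(3, -8, 11), `+`)
    rigid$subunits[[j]]$xyz <- array(c(xyz1[[j]], moved),
                                     dim = c(nrow(moved), 3, 2))
  }
  rigid$n_frames <- 2L
  rs <- rmsd_series(rigid, positions(rigid), reference = 1L)
  expect_lt(max(rs$rmsd_angstrom), 1e-8)

  ## Single-atom displacement delta: post-fit RMSD <= delta / sqrt(N).
  delta <- 3
  shifted <- rigid
  shifted$subunits[[1]]$xyz[, , 2] <- xyz1[[1]]
  for (j in 2:4) shifted$subunits[[j]]$xyz[, , 2] <- xyz1[[j]]
  shifted$subunits[[1]]$xyz[1, 3, 2] <- xyz1[[1]][1, 3] + delta
  rs2 <- rmsd_series(shifted, positions(shifted), reference = 1L)
  n_atoms <- sum(vapply(shifted$subunits, function(s) dim(s$xyz)[1], 1L))
  expect_gt(rs2$rmsd_angstrom[2], 0)
  expect_lte(rs2$rmsd_angstrom[2], delta / sqrt(n_atoms) + 1e-12)
  ## External reference covering the selection.
  rs3 <- rmsd_series(base, c(2L, 3L), reference = base)
  expect_lt(rs3$rmsd_angstrom[1], 1e-12)
  expect_error(rmsd_series(base, 1:4, reference = make_bare_filament(2)),
               class = "cofilactin_input_error")
})

test_that("per-position statistics use the trailing window with population SD", {
  prof <- angle_profile("twist", 1L, matrix(c(5, 1, 2, 3), nrow = 1))
  st <- per_position_stats(prof, last_k = 3)
  expect_equal(st$mean, 2)
  expect_equal(st$sd, sqrt(2 / 3))
  ## Constant frames: SD 0; full window equals full-series stats.
  prof2 <- angle_profile("twist", 1:2, matrix(7, 2, 5))
  st2 <- per_position_stats(prof2, last_k = 5)
  expect_true(all(st2$sd == 0))
  full <- per_position_stats(prof, last_k = 4)
  expect_equal(full$mean, mean(c(5, 1, 2, 3)))
  expect_error(per_position_stats(prof, last_k = 0),
               class = "cofilactin_config_error")
  expect_error(per_position_stats(prof, last_k = 9),
               class = "cofilactin_config_error")
})

test_that("all observables are invariant under a global rigid motion", {
  sys <- make_filament(bare_actin_template(), n_subunits = 6,
                       helical = helical_params(c(rep(167, 2), rep(162, 3))),
                       occupancy = 2L,
                       noise = noise_model(0.3, 2, seed = 21))
  R <- random_rotation(33)
  moved <- transform_system(sys, R, c(40, -15, 60))

  tw0 <- twist_profile(sys); tw1 <- twist_profile(moved)
  expect_lt(max(abs(tw0$values - tw1$values)), 1e-8)

  for (n in positions(sys)) {
    g0 <- flatness_and_cleft(sys, 2, n)
    g1 <- flatness_and_cleft(moved, 2, n)
    expect_lt(abs(g0$phi - g1$phi), 1e-8)
    expect_lt(abs(g0$d - g1$d), 1e-8)
  }
  c0 <- dloop_contact_profile(sys); c1 <- dloop_contact_profile(moved)
  expect_identical(c0$values, c1$values)
  r0 <- rmsd_series(sys, positions(sys), 1L)
  r1 <- rmsd_series(moved, positions(moved), 1L)
  expect_lt(max(abs(r0$rmsd_angstrom - r1$rmsd_angstrom)), 1e-8)
})

test_that("mean twist under coordinate noise recovers the prescribed value", {
  sys <- make_filament(bare_actin_template(), n_subunits = 18,
                       helical = helical_params(167),
                       noise = noise_model(0.5, 200, seed = 77))
  tw <- twist_profile(sys)
  se <- tw$sd / sqrt(ncol(tw$values))
  expect_true(all(abs(tw$mean - 167) <= 3 * se))
})
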