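test_that("template generator round-trips flatness and cleft targets", {
  for (phi in c(-30, -20, -10, 0)) {
    for (d in c(24, 25)) {
      tpl <- make_subunit_template(phi, d, seed = 101)
      sys <- make_filament(tpl, n_subunits = 1)
      g <- flatness_and_cleft(sys, 1, 1)
      expect_lt(abs(g$phi - phi), 1e-6)
      expect_lt(abs(g$d - d), 1e-6)
    }
  }
})

test_that("template generation is seed-deterministic", {
  a <- make_subunit_template(-29, 25, seed = 5)
  b <- make_subunit_template(-29, 25, seed = 5)
  expect_identical(a$ca_coords, b$ca_coords)
  c <- make_subunit_template(-29, 25, seed = 6)
  expect_false(identical(a$ca_coords, c$ca_coords))
})

test_that("unreachable template geometries are rejected", {
  expect_error(make_subunit_template(-29, 3, seed = 1),
               class = "cofilactin_generation_error")
  expect_error(make_subunit_template(95, 25, seed = 1),
               class = "cofilactin_config_error")
  expect_error(make_subunit_template(-29, -1, seed = 1),
               class = "cofilactin_config_error")
})

test_that("filament generator realises prescribed helical symmetry", {
  ## Uniform twist round trip, zero noise.
  sys <- make_filament(bare_actin_template(), n_subunits = 18,
                       helical = helical_params(162))
  tw <- twist_profile(sys)
  expect_true(all(abs(tw$mean - 162) < 1e-6))

  ## Position-dependent twist is realised pair by pair.
  steps <- c(rep(167, 8), rep(162, 9))
  sys2 <- make_filament(bare_actin_template(), n_subunits = 18,
                        helical = helical_params(steps))
  tw2 <- twist_profile(sys2)
  expect_true(all(abs(tw2$mean - steps) < 1e-6))
})

test_that("noise model controls frame structure deterministically", {
  tpl <- bare_actin_template()
  ## Zero noise: all frames identical.
  s0 <- make_filament(tpl, n_subunits = 4,
                      noise = noise_model(0, 3, seed = 2))
  expect_identical(s0$subunits[[1]]$xyz[, , 1], s0$subunits[[1]]$xyz[, , 3])
  ## Same seed: bitwise identical; different seed: different.
  s1 <- make_filament(tpl, n_subunits = 4,
                      noise = noise_model(0.5, 2, seed = 3))
  s2 <- make_filament(tpl, n_subunits = 4,
                      noise = noise_model(0.5, 2, seed = 3))
  s3 <- make_filament(tpl, n_subunits = 4,
                      noise = noise_model(0.5, 2, seed = 4))
  expect_identical(s1$subunits[[2]]$xyz, s2$subunits[[2]]$xyz)
  expect_false(identical(s1$subunits[[2]]$xyz, s3$subunits[[2]]$xyz))
  expect_false(identical(s1$subunits[[2]]$xyz[, , 1],
                         s1$subunits[[2]]$xyz[, , 2]))
})

test_that("angle-profile generator matches the transition model", {
  slow <- transition_params(165.1, 155.1, 1.4, 1.1)
  ## Barbed-side asymptote.
  p <- make_angle_profile(slow, c(-1000L, -999L))
  expect_lt(abs(p$mean[1] - 165.1), 1e-9)
  ## Sigmoid midpoint at n = n0 (evaluated off-grid directly).
  expect_equal(evaluate_transition(slow, 1.4), (165.1 + 155.1) / 2)
  expect_error(make_angle_profile(slow, integer(0)),
               class = "cofilactin_config_error")
})

test_that("per-position SD of noisy profiles converges to the noise SD", {
  slow <- transition_params(165.1, 155.1, 1.4, 1.1)
  prof <- make_angle_profile(slow, -8:9, noise_sd = 2.0, n_frames = 2000,
                             seed = 31)
  expect_true(all(abs(prof$sd - 2.0) / 2.0 < 0.05))
})
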