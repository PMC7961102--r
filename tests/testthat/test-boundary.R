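bare18 <- make_bare_filament(18)
cof12 <- make_cofilactin_filament(12)

test_that("boundary splicing yields 18 actins and 8 cofilins in both modes", {
  for (mode in c("slow", "fast")) {
    b <- splice_boundary(bare18, cof12, mode)
    expect_identical(n_subunits(b), 18L)
    expect_identical(n_cofilins(b), 8L)
    expect_identical(range(positions(b)), c(-8L, 9L))
    expect_identical(b$interfacial_index, 0L)
    ## Interfacial subunits i and i+1 each contact exactly one cofilin.
    expect_length(cofilins_touching(b, 0), 1L)
    expect_length(cofilins_touching(b, 1), 1L)
    ## Retention rule: every kept cofilin's bridged pair lies inside the
    ## cofilactin-side segment.
    cof_side <- if (mode == "slow") 0:9 else -8:1
    for (rec in b$occupancy) {
      expect_true(all(rec$pair %in% cof_side))
    }
    expect_identical(b$boundary$mode, mode)
  }
  ## Occupancy is mirror-ordered between the two modes.
  slow <- splice_boundary(bare18, cof12, "slow")
  fast <- splice_boundary(bare18, cof12, "fast")
  expect_identical(cofilin_keys(slow), 0:7)
  expect_identical(cofilin_keys(fast), -8:-1)
  expect_false(slow$boundary$requires_relaxation)
  expect_true(fast$boundary$requires_relaxation)
})

test_that("spliced segments keep their source conformations and twists", {
  slow <- splice_boundary(bare18, cof12, "slow")
  tw <- twist_profile(slow)
  ## Interior pairs of each segment retain the generating twist.
  bare_side <- tw$mean[tw$positions <= -2]
  cof_side <- tw$mean[tw$positions >= 0]
  expect_true(all(abs(bare_side - 167) < 1e-6))
  expect_true(all(abs(cof_side - 162) < 1e-6))
  ## Interfacial subunits carry the cofilactin-like conformation label.
  expect_identical(get_subunit_label(slow, 0), "cofilactin")
  expect_identical(get_subunit_label(slow, -1), "bare")
})

test_that("alternative fast construction is available but distinct", {
  alt <- splice_boundary(bare18, cof12, "fast_alt")
  expect_identical(n_subunits(alt), 18L)
  expect_identical(alt$boundary$mode, "fast_alt")
  ## Interfacial actin starts actin-like here.
  expect_identical(get_subunit_label(alt, 0), "bare")
})

test_that("splicing preconditions are enforced", {
  expect_error(splice_boundary(make_bare_filament(5), cof12, "slow"),
               regexp = "at least 10 subunits",
               class = "cofilactin_topology_error")
  expect_error(splice_boundary(bare18, make_cofilactin_filament(11), "fast"),
               class = "cofilactin_topology_error")
  expect_error(splice_boundary(bare18, make_bare_filament(12), "slow"),
               class = "cofilactin_topology_error")  # no occupancy
})

test_that("longitudinal replication doubles an 11-subunit cofilactin repeat", {
  cof11 <- make_cofilactin_filament(11)
  expect_identical(n_subunits(cof11), 11L)
  expect_identical(n_cofilins(cof11), 10L)
  rep1 <- replicate_longitudinal(cof11, times = 1)
  expect_identical(n_subunits(rep1), 22L)
  expect_identical(n_cofilins(rep1), 20L)
  expect_identical(cofilin_keys(rep1), c(1:10, 12:21))
  ## times = 0 is the identity; times = 2 triples.
  expect_identical(replicate_longitudinal(cof11, 0), cof11)
  rep2 <- replicate_longitudinal(cof11, 2)
  expect_identical(n_subunits(rep2), 33L)
  expect_identical(n_cofilins(rep2), 30L)
})

test_that("replication preserves the helical twist across the junction", {
  cof11 <- make_cofilactin_filament(11)
  rep1 <- replicate_longitudinal(cof11, 1)
  tw <- twist_profile(rep1)
  junction <- tw$mean[tw$positions == 11]
  interior <- tw$mean[tw$positions != 11]
  expect_lt(abs(junction - 162), 1e-6)
  expect_true(all(abs(interior - junction) < 1e-6))
})

test_that("non-periodic inputs are rejected by replication", {
  noisy <- make_filament(cofilactin_actin_template(), n_subunits = 6,
                         helical = helical_params(162),
                         noise = noise_model(2.5, 1, seed = 8))
  expect_error(replicate_longitudinal(noisy, 1, tol = 0.5),
               class = "cofilactin_topology_error")
})

test_that("cofilin ablation removes occupancy without touching actin", {
  sys <- replicate_longitudinal(make_cofilactin_filament(11), 1)
  ## Full ablation.
  none <- ablate_cofilins(sys, integer(0))
  expect_identical(n_cofilins(none), 0L)
  expect_identical(none$subunits, sys$subunits)   # bitwise unchanged
  ## n = 2 longitudinal cluster {k, k+2} and lateral cluster {k, k+1}.
  lon <- ablate_cofilins(sys, c(8L, 10L))
  expect_identical(cofilin_clusters(lon), list(c(8L, 10L)))
  lat <- ablate_cofilins(sys, c(8L, 9L))
  expect_identical(cofilin_clusters(lat), list(c(8L, 9L)))
  sep <- ablate_cofilins(sys, c(3L, 9L))
  expect_length(cofilin_clusters(sep), 2L)
  ## keep = full set is the identity.
  expect_identical(ablate_cofilins(sys, cofilin_keys(sys)), sys)
  expect_error(ablate_cofilins(sys, 99L),
               class = "cofilactin_topology_error")
})
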