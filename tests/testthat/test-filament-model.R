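test_that("default residue selections resolve to the canonical ranges", {
  tpl <- bare_actin_template()
  dl <- resolve_selection("dloop", tpl)
  expect_identical(dl, 44:52)
  expect_length(dl, 9L)
  tc <- resolve_selection("target_cleft", tpl)
  expect_identical(tc, c(143:148, 349:351))
  expect_length(tc, 9L)

  sds <- lapply(c("sd1", "sd2", "sd3", "sd4"), resolve_selection,
                subunit = tpl)
  expect_identical(sort(unlist(sds)), 1:375)
  expect_true(all(dl %in% sds[[2]]))

  ## Resolution is idempotent and order-independent.
  expect_identical(resolve_selection("dloop", tpl), dl)
  shuffled <- residue_selections(dloop = sample(44:52))
  tpl2 <- make_subunit_template(-9, 25, selections = shuffled)
  expect_identical(resolve_selection("dloop", tpl2), dl)
})

test_that("selection errors are typed and informative", {
  tpl <- bare_actin_template()
  expect_error(resolve_selection("nonesuch", tpl),
               class = "cofilactin_config_error")
  expect_error(resolve_selection("dloop", cofilin_template()),
               class = "cofilactin_structural_error")
})

test_that("selection validation rejects inconsistent partitions", {
  ## Overlapping subdomains.
  expect_error(
    residue_selections(subdomains = list(sd1 = 1:40, sd2 = 33:69,
                                         sd3 = 70:200, sd4 = 201:375)),
    class = "cofilactin_config_error"
  )
  ## D-loop outside SD2.
  expect_error(residue_selections(dloop = 1:9),
               class = "cofilactin_config_error")
  ## Gap in the residue coverage.
  expect_error(
    residue_selections(subdomains = list(sd1 = 1:32, sd2 = 33:69,
                                         sd3 = 80:200, sd4 = 201:375)),
    class = "cofilactin_config_error"
  )
})

test_that("neighbor rules follow the genetic-helix topology", {
  sys <- make_bare_filament(18)
  expect_identical(neighbor(sys, 5, "longitudinal-pointed"), 7L)
  expect_identical(neighbor(sys, 5, "longitudinal-barbed"), 3L)
  expect_identical(neighbor(sys, 5, "lateral"), 6L)
  ## Two lateral steps equal one longitudinal step.
  expect_identical(neighbor(sys, neighbor(sys, 5, "lateral"), "lateral"),
                   neighbor(sys, 5, "longitudinal-pointed"))
  ## Boundary of the list.
  expect_true(is.na(neighbor(sys, 18, "longitudinal-pointed")))
  expect_true(is.na(neighbor(sys, 1, "longitudinal-barbed")))
  expect_error(neighbor(sys, 5, "sideways"),
               class = "cofilactin_config_error")
})

test_that("putative severing interfaces sit on the bare side of the interfacial subunits", {
  slow <- boundary_spec("slow", 8, 10, 8, interfacial_index = 0)
  expect_equal(unname(putative_severing_interface(slow)),
               rbind(c(-2L, 0L), c(-1L, 1L)))
  fast <- boundary_spec("fast", 8, 10, 8, interfacial_index = 0)
  expect_equal(unname(putative_severing_interface(fast)),
               rbind(c(0L, 2L), c(1L, 3L)))
  expect_error(boundary_spec(NA, 8, 10, 8, 0),
               class = "cofilactin_config_error")
  expect_error(putative_severing_interface(list(mode = "slow")),
               class = "cofilactin_config_error")
})

test_that("filament system construction enforces the occupancy topology", {
  tpl <- bare_actin_template()
  ## Cofilin bridging past the pointed end: rejected unless periodic.
  expect_error(
    make_filament(tpl, n_subunits = 5, occupancy = 4L),
    class = "cofilactin_topology_error"
  )
  sys <- make_filament(tpl, n_subunits = 5, occupancy = 4L, periodic = TRUE)
  expect_identical(cofilin_keys(sys), 4L)
  ## Every non-dangling cofilin's bridged pair exists.
  cof <- make_cofilactin_filament(11)
  for (rec in cof$occupancy) {
    expect_true(rec$pair[1] %in% positions(cof))
    expect_true(rec$pair[2] %in% positions(cof) || cof$periodic)
  }
  expect_identical(cofilins_touching(cof, 5), c(3L, 5L))
})
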