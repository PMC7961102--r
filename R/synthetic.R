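# Synthetic-filament generator. Emulates, at the C-alpha level, the
# statistical structure of equilibrated filament ensembles: helical symmetry
# with prescribed per-subunit twist and rise, per-subunit internal
# conformation set by the flatness dihedral phi and the cleft distance d,
# cofilin placeholders bridging longitudinal pairs, and i.i.d. Gaussian
# coordinate noise across frames.

#' Helical symmetry parameters
#'
#' @param twist_per_subunit Rotation magnitude between consecutive genetic-
#'   helix subunits, degrees in (0, 180]. May be a vector (one value per
#'   adjacent pair) to realise position-dependent twist across a boundary.
#' @param rise_per_subunit Axial rise per subunit, Angstrom (default 27.5,
#'   the canonical actin value).
#' @return Object of class `helical_params`.
#' @export
helical_params <- function(twist_per_subunit, rise_per_subunit = 27.5) {
  if (any(twist_per_subunit <= 0) || any(twist_per_subunit > 180)) {
    stop_config("twist_per_subunit must lie in (0, 180] degrees")
  }
  if (rise_per_subunit <= 0) stop_config("rise_per_subunit must be positive")
  structure(
    list(twist_per_subunit = as.numeric(twist_per_subunit),
         rise_per_subunit = as.numeric(rise_per_subunit)),
    class = "helical_params"
  )
}

#' Frame-noise model
#'
#' @param coordinate_sd Gaussian SD per Cartesian component, Angstrom (>= 0).
#' @param n_frames Number of frames to generate (>= 1).
#' @param seed Integer RNG seed.
#' @return Object of class `noise_model`.
#' @export
noise_model <- function(coordinate_sd = 0, n_frames = 1L, seed = 1L) {
  if (coordinate_sd < 0) stop_config("coordinate_sd must be >= 0")
  if (n_frames < 1L) stop_config("n_frames must be >= 1")
  structure(
    list(coordinate_sd = as.numeric(coordinate_sd),
         n_frames = as.integer(n_frames), seed = as.integer(seed)),
    class = "noise_model"
  )
}

## Fixed local-frame anchors of the subdomain center-of-mass scaffold.
## Filament axis is +z (barbed -> pointed), x is radial. SD3/SD4 form the
## inner longitudinal column; SD1/SD2 are the outer domain, with SD2
## (carrying the D-loop) dangling from SD1 at the dihedral angle phi about
## the SD1-SD3 axis.
.template_anchors <- function() {
  list(c1 = c(24, 0, -8), c3 = c(8, 0, -20), c4 = c(8, 0, 20), h2 = 20)
}

#' Generate a synthetic actin subunit template
#'
#' Places 375 C-alpha pseudo-coordinates as four compact subdomain clusters
#' whose centers of mass realise a prescribed flatness dihedral
#' phi = dihedral(COM(SD2), COM(SD1), COM(SD3), COM(SD4)) and cleft distance
#' d = |COM(SD2) - COM(SD4)| exactly (to floating-point precision), so that
#' [flatness_and_cleft()] round-trips the targets. D-loop residues sit on a
#' protrusion extending toward the pointed end when `dloop = "extended"`
#' (bare-actin-like) or tucked into the SD2 body when `"retracted"`
#' (cofilactin-like, no longitudinal D-loop contact).
#'
#' @param phi_target Flatness dihedral, degrees, |phi| < 90.
#' @param d_target Cleft distance, Angstrom.
#' @param seed Integer seed; identical inputs and seed give bitwise-identical
#'   coordinates.
#' @param dloop `"extended"` or `"retracted"`.
#' @param conformation_label Label stored on the template.
#' @param selections A [residue_selections()]; also fixes the residue count.
#' @param cluster_sd Spread of each subdomain cluster, Angstrom.
#' @return A [subunit_template()] of kind `"actin"`.
#' @export
make_subunit_template <- function(phi_target, d_target, seed = 1L,
                                  dloop = c("extended", "retracted"),
                                  conformation_label = "custom",
                                  selections = residue_selections(),
                                  cluster_sd = 2.5) {
  dloop <- match.arg(dloop)
  if (abs(phi_target) >= 90) stop_config("|phi_target| must be < 90 degrees")
  if (d_target <= 0) stop_config("d_target must be positive")

  an <- .template_anchors()
  e <- unit(an$c3 - an$c1)                       # dihedral axis SD1 -> SD3
  perp4 <- (an$c4 - an$c3) - sum((an$c4 - an$c3) * e) * e
  q1 <- unit(perp4)                              # half-plane of SD4
  q2 <- vcross(e, q1)
  base <- an$c1 - an$h2 * e                      # on the axis, pointedward

  ## Rotating SD2's half-plane by +beta about e changes the measured
  ## dihedral linearly; determine the sign of that relationship once.
  probe <- base + 10 * (cos(deg2rad(10)) * q1 + sin(deg2rad(10)) * q2)
  sgn <- sign(dihedral_angle(probe, an$c1, an$c3, an$c4) )
  phi_rot <- sgn * phi_target

  w <- cos(deg2rad(phi_rot)) * q1 + sin(deg2rad(phi_rot)) * q2
  v <- base - an$c4
  vw <- sum(v * w)
  disc <- vw^2 - (sum(v^2) - d_target^2)
  if (disc < 0) {
    stop_generation(sprintf(
      "unreachable geometry: cleft distance %.2f A below the minimum %.2f A for phi = %.1f",
      d_target, sqrt(sum(v^2) - vw^2), phi_target
    ))
  }
  roots <- c(-vw - sqrt(disc), -vw + sqrt(disc))
  roots <- roots[roots > 2 * cluster_sd]
  if (length(roots) == 0L) {
    stop_generation("unreachable geometry: d_target smaller than cluster radii")
  }
  r2 <- min(roots)
  c2 <- base + r2 * w

  n_by_sd <- vapply(selections[c("sd1", "sd2", "sd3", "sd4")], length, 1L)
  n_res <- sum(n_by_sd)
  coords <- matrix(NA_real_, n_res, 3)

  set.seed(seed)
  coords[selections$sd1, ] <- gauss_cluster(n_by_sd[1], an$c1, cluster_sd)
  coords[selections$sd3, ] <- gauss_cluster(n_by_sd[3], an$c3, cluster_sd)
  coords[selections$sd4, ] <- gauss_cluster(n_by_sd[4], an$c4, cluster_sd)

  ## SD2 assembled in the phi = 0 half-plane, then rotated about the
  ## SD1-SD3 axis into place; the D-loop rides with the outer domain.
  c2_0 <- base + r2 * q1
  dl_offset <- if (dloop == "extended") c(-20, 0, 16) else c(0, 0, 0)
  dl_center0 <- c2_0 + dl_offset
  dl_ids <- selections$dloop
  core_ids <- setdiff(selections$sd2, dl_ids)
  n_dl <- length(dl_ids)
  n_core <- length(core_ids)
  core_center0 <- (n_by_sd[2] * c2_0 - n_dl * dl_center0) / n_core
  sd2_pts <- matrix(NA_real_, n_by_sd[2], 3)
  rownames(sd2_pts) <- as.character(selections$sd2)
  sd2_pts[as.character(dl_ids), ] <- gauss_cluster(n_dl, dl_center0, 1.2)
  sd2_pts[as.character(core_ids), ] <- gauss_cluster(n_core, core_center0,
                                                     cluster_sd)
  sd2_pts <- rotate_about(sd2_pts, an$c1, e, phi_rot)
  coords[selections$sd2, ] <- sd2_pts

  subunit_template(coords, kind = "actin",
                   conformation_label = conformation_label,
                   selections = selections)
}

#' Default bare-actin-like template (flat subunit, extended D-loop)
#'
#' Flatness set to the bare-side asymptote of the slow-boundary transition
#' (-9 degrees); cleft distance 25 Angstrom.
#' @param seed Integer seed.
#' @return A [subunit_template()].
#' @export
bare_actin_template <- function(seed = 42L) {
  make_subunit_template(-9.0, 25.0, seed = seed, dloop = "extended",
                        conformation_label = "bare")
}

#' Default cofilactin-like template (twisted subunit, retracted D-loop)
#'
#' Flatness set to the cofilactin-side asymptote of the slow-boundary
#' transition (-28.9 degrees); cleft distance 24 Angstrom.
#' @param seed Integer seed.
#' @return A [subunit_template()].
#' @export
cofilactin_actin_template <- function(seed = 43L) {
  make_subunit_template(-28.9, 24.0, seed = seed, dloop = "retracted",
                        conformation_label = "cofilactin")
}

#' Cofilin placeholder template
#'
#' A compact ~150-residue C-alpha blob (ball of radius ~12 Angstrom) centered
#' at the origin. It exists for occupancy topology and bridge-contact tests,
#' not for structural realism.
#'
#' @param seed Integer seed.
#' @param n_residues Number of pseudo-residues.
#' @param radius Ball radius, Angstrom.
#' @return A [subunit_template()] of kind `"cofilin"`.
#' @export
cofilin_template <- function(seed = 7L, n_residues = 150L, radius = 12) {
  set.seed(seed)
  dir <- matrix(stats::rnorm(3L * n_residues), ncol = 3)
  dir <- dir / sqrt(rowSums(dir^2))
  r <- radius * stats::runif(n_residues)^(1 / 3)
  pts <- dir * r
  pts <- sweep(pts, 2, colMeans(pts))
  subunit_template(pts, kind = "cofilin", conformation_label = "cofilin")
}

## Center-of-mass of a named selection on one subunit's coordinates.
selection_com <- function(template, xyz, name) {
  idx <- match(resolve_selection(name, template), template$residue_ids)
  colMeans(xyz[idx, , drop = FALSE])
}

#' Generate a synthetic filament
#'
#' Subunit n+1 is subunit n's template rotated by twist(n) about the filament
#' axis (+z) and raised along it; twist may vary by position to realise a
#' boundary. Cofilin placeholders are centered between SD2 of the barbed-side
#' and SD1 of the pointed-side bridged actin. Frames are the ideal
#' coordinates plus i.i.d. Gaussian noise (seeded).
#'
#' @param templates A single actin [subunit_template()] (recycled) or a list
#'   with one template per subunit position.
#' @param n_subunits Number of actin subunits (inferred from a template list).
#' @param helical A [helical_params()]; the twist component may be a vector
#'   of length `n_subunits - 1`.
#' @param occupancy Integer vector of cofilin keys k, each bridging actins
#'   (k, k+2). With `periodic = TRUE`, keys whose partner k+2 lies just past
#'   the pointed end are allowed (they bridge into the next periodic image).
#' @param noise A [noise_model()].
#' @param periodic Mark the output as a periodic repeat.
#' @param cofilin A cofilin [subunit_template()] used for all placeholders.
#' @return A [filament_system()].
#' @export
make_filament <- function(templates, n_subunits = NULL,
                          helical = helical_params(167),
                          occupancy = integer(0),
                          noise = noise_model(),
                          periodic = FALSE,
                          cofilin = cofilin_template()) {
  if (inherits(templates, "subunit_template")) {
    if (is.null(n_subunits)) {
      stop_config("n_subunits is required with a single template")
    }
    templates <- rep(list(templates), n_subunits)
  }
  n <- length(templates)
  if (n < 1L) stop_topology("a filament needs >= 1 subunit")

  twist <- helical$twist_per_subunit
  if (length(twist) == 1L) twist <- rep(twist, max(n - 1L, 1L))
  if (length(twist) < n - 1L) {
    stop_config("twist vector must have one value per adjacent pair")
  }
  ## Extend by the terminal step so virtual pointed-end images (used for
  ## dangling-cofilin placement) are well defined.
  twist_ext <- c(twist, rep(twist[length(twist)], 2L))
  rise <- helical$rise_per_subunit
  cum_ang <- cumsum(c(0, twist_ext))

  ideal_at <- function(p, tpl) {
    sweep(tpl$ca_coords %*% t(rot_z(cum_ang[p])), 2,
          c(0, 0, (p - 1) * rise), `+`)
  }
  ideal <- lapply(seq_len(n), function(p) ideal_at(p, templates[[p]]))

  occupancy <- sort(unique(as.integer(occupancy)))
  max_key <- if (periodic) n else n - 2L
  if (length(occupancy) &&
      (any(occupancy < 1L) || any(occupancy > max_key))) {
    stop_topology("cofilin occupancy references absent subunits")
  }
  cof_ideal <- lapply(occupancy, function(k) {
    barbed <- selection_com(templates[[k]], ideal[[k]], "sd2")
    pt_tpl <- templates[[((k + 1L) %% n) + 1L]]
    pointed_xyz <- if (k + 2L <= n) ideal[[k + 2L]] else
      ideal_at(k + 2L, pt_tpl)
    pointed <- selection_com(
      if (k + 2L <= n) templates[[k + 2L]] else pt_tpl, pointed_xyz, "sd1")
    center <- (barbed + pointed) / 2
    sweep(cofilin$ca_coords, 2, center, `+`)
  })

  nf <- noise$n_frames
  sdv <- noise$coordinate_sd
  set.seed(noise$seed)
  add_noise <- function(m) {
    if (sdv == 0) m else m + matrix(stats::rnorm(length(m), sd = sdv),
                                    nrow = nrow(m))
  }
  sub_arr <- lapply(seq_len(n), function(p) {
    array(NA_real_, dim = c(nrow(ideal[[p]]), 3L, nf))
  })
  cof_arr <- lapply(seq_along(occupancy), function(j) {
    array(NA_real_, dim = c(nrow(cof_ideal[[j]]), 3L, nf))
  })
  for (f in seq_len(nf)) {
    for (p in seq_len(n)) sub_arr[[p]][, , f] <- add_noise(ideal[[p]])
    for (j in seq_along(occupancy)) {
      cof_arr[[j]][, , f] <- add_noise(cof_ideal[[j]])
    }
  }

  subs <- lapply(seq_len(n), function(p) {
    make_subunit_entry(p, templates[[p]], sub_arr[[p]])
  })
  cofs <- lapply(seq_along(occupancy), function(j) {
    make_cofilin_record(occupancy[j], cofilin, cof_arr[[j]])
  })
  filament_system(subs, cofs, periodic = periodic)
}

#' Bare-actin synthetic filament
#'
#' @param n_subunits Subunit count (default 18).
#' @param twist Per-subunit twist, degrees (default 167, the bare-actin
#'   cryo-EM value).
#' @param noise A [noise_model()].
#' @param template Actin template (default [bare_actin_template()]).
#' @return A [filament_system()].
#' @export
make_bare_filament <- function(n_subunits = 18L, twist = 167,
                               noise = noise_model(),
                               template = bare_actin_template()) {
  make_filament(template, n_subunits = n_subunits,
                helical = helical_params(twist), noise = noise)
}

#' Fully decorated cofilactin synthetic filament
#'
#' A periodic cofilactin repeat: n subunits with cofilins keyed 1..(n-1);
#' the pointed-most cofilin bridges into the next periodic image (matching
#' the stoichiometry that yields 20 cofilins when an 11-subunit repeat is
#' replicated once to 22 subunits).
#'
#' @param n_subunits Subunit count (default 11).
#' @param twist Per-subunit twist, degrees (default 162, the cofilactin
#'   cryo-EM value).
#' @param noise A [noise_model()].
#' @param template Actin template (default [cofilactin_actin_template()]).
#' @return A periodic [filament_system()] with `n_subunits - 1` cofilins.
#' @export
make_cofilactin_filament <- function(n_subunits = 11L, twist = 162,
                                     noise = noise_model(),
                                     template = cofilactin_actin_template()) {
  make_filament(template, n_subunits = n_subunits,
                helical = helical_params(twist),
                occupancy = seq_len(n_subunits - 1L),
                noise = noise, periodic = TRUE)
}

#' Generate an angle profile from the boundary transition model
#'
#' Draws per-position, per-frame values theta(n) + Gaussian noise, where
#' theta is the sigmoid crossover model evaluated by
#' [evaluate_transition()]. Used to test the fitter against known truth.
#'
#' @param params A [transition_params()].
#' @param positions Integer vector of subunit positions (non-empty).
#' @param noise_sd Gaussian noise SD, degrees.
#' @param n_frames Frames to draw.
#' @param seed Integer seed.
#' @param observable Label for the profile.
#' @return An [angle_profile()].
#' @export
make_angle_profile <- function(params, positions, noise_sd = 0,
                               n_frames = 1L, seed = 1L,
                               observable = "twist") {
  if (length(positions) == 0L) stop_config("positions must be non-empty")
  mu <- evaluate_transition(params, positions)
  set.seed(seed)
  vals <- matrix(mu, nrow = length(positions), ncol = n_frames) +
    matrix(stats::rnorm(length(positions) * n_frames, sd = noise_sd),
           nrow = length(positions))
  angle_profile(observable, positions, vals)
}
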