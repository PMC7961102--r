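# Per-subunit observables: adjacent-subunit twist, flatness dihedral phi,
# cleft distance d, C-alpha contact counts, interface integrity and RMSD.

.check_frames <- function(system, frames) {
  if (is.null(frames)) return(seq_len(system$n_frames))
  frames <- as.integer(frames)
  if (any(frames < 1L) || any(frames > system$n_frames)) {
    stop_input("frame selection out of range")
  }
  frames
}

#' Adjacent-subunit twist profile
#'
#' For each adjacent pair (n, n+1) the relative screw-transform rotation
#' angle is extracted: the SD3+SD4 (inner rigid core) C-alpha sets of the
#' two subunits are superposed and the rotation angle
#' theta = arccos((trace(R) - 1)/2) is reported in degrees, magnitude in
#' (0, 180], stored at position n. An alternative azimuthal-projection
#' estimator (rotation of the subunit center of mass about the filament
#' axis) is available for sensitivity checks.
#'
#' @param system A [filament_system()].
#' @param frames Frame indices (default all).
#' @param method `"screw"` (default) or `"azimuth"`.
#' @return An [angle_profile()] with observable `"twist"`.
#' @export
twist_profile <- function(system, frames = NULL,
                          method = c("screw", "azimuth")) {
  method <- match.arg(method)
  frames <- .check_frames(system, frames)
  pos <- positions(system)
  if (length(pos) < 2L) stop_input("twist needs >= 2 subunits")
  pair_pos <- pos[-length(pos)]
  vals <- matrix(NA_real_, length(pair_pos), length(frames))

  if (method == "screw") {
    core_idx <- lapply(system$subunits, function(s) {
      if (is.null(s$template$selections)) {
        stop_config("subunit lacks the SD3+SD4 rigid-core selection")
      }
      core <- c(resolve_selection("sd3", s$template),
                resolve_selection("sd4", s$template))
      match(core, s$template$residue_ids)
    })
    for (j in seq_along(pair_pos)) {
      ia <- j
      ib <- j + 1L
      if (length(core_idx[[ia]]) != length(core_idx[[ib]])) {
        stop_config("adjacent subunits do not share a common rigid core")
      }
      for (f in seq_along(frames)) {
        a <- system$subunits[[ia]]$xyz[core_idx[[ia]], , frames[f]]
        b <- system$subunits[[ib]]$xyz[core_idx[[ib]], , frames[f]]
        tf <- superpose(b, a)
        vals[j, f] <- rotation_angle(tf$rotation)
      }
    }
  } else {
    for (f in seq_along(frames)) {
      coms <- t(vapply(system$subunits, function(s) {
        colMeans(s$xyz[, , frames[f], drop = TRUE])
      }, numeric(3)))
      ctr <- colMeans(coms)
      ax <- svd(sweep(coms, 2, ctr))$v[, 1]
      b1 <- unit(vcross(ax, if (abs(ax[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)))
      b2 <- vcross(ax, b1)
      rel <- sweep(coms, 2, ctr)
      az <- atan2(rel %*% b2, rel %*% b1) * 180 / pi
      d <- diff(as.numeric(az))
      d <- (d + 180) %% 360 - 180
      vals[, f] <- abs(d)
    }
  }
  angle_profile("twist", pair_pos, vals)
}

#' Flatness dihedral and cleft distance of one subunit
#'
#' Computes the centers of mass (uniform C-alpha weights) of subdomains
#' SD1..SD4 and reports the flatness angle
#' phi = signed dihedral of (COM(SD2), COM(SD1), COM(SD3), COM(SD4))
#' (right-hand IUPAC torsion convention) and the cleft distance
#' d = |COM(SD2) - COM(SD4)|.
#'
#' @param system A [filament_system()].
#' @param frame Frame index.
#' @param n Subunit position (must be actin with subdomain selections).
#' @return List of class `subunit_geometry`: `position`, `frame`, `phi`
#'   (degrees), `d` (Angstrom).
#' @export
flatness_and_cleft <- function(system, frame = 1L, n) {
  s <- get_subunit(system, n)
  if (s$template$kind != "actin") {
    stop_domain("flatness is defined for actin subunits only")
  }
  xyz <- subunit_coords(system, n, frame)
  com <- function(sel) {
    idx <- match(resolve_selection(sel, s$template), s$template$residue_ids)
    colMeans(xyz[idx, , drop = FALSE])
  }
  c1 <- com("sd1"); c2 <- com("sd2"); c3 <- com("sd3"); c4 <- com("sd4")
  structure(
    list(position = n, frame = frame,
         phi = dihedral_angle(c2, c1, c3, c4),
         d = vnorm(c2 - c4)),
    class = "subunit_geometry"
  )
}

#' Flatness-angle profile across the filament
#'
#' @param system A [filament_system()].
#' @param frames Frame indices (default all).
#' @return An [angle_profile()] with observable `"phi"`.
#' @export
phi_profile <- function(system, frames = NULL) {
  frames <- .check_frames(system, frames)
  pos <- positions(system)
  vals <- matrix(NA_real_, length(pos), length(frames))
  for (j in seq_along(pos)) {
    for (f in seq_along(frames)) {
      vals[j, f] <- flatness_and_cleft(system, frames[f], pos[j])$phi
    }
  }
  angle_profile("phi", pos, vals)
}

#' Per-subunit geometry table (phi and d)
#'
#' @param system A [filament_system()].
#' @param frames Frame indices (default all).
#' @return `data.frame` with columns `frame`, `position_n`, `phi_deg`,
#'   `d_angstrom`.
#' @export
geometry_records <- function(system, frames = NULL) {
  frames <- .check_frames(system, frames)
  pos <- positions(system)
  out <- expand.grid(position_n = pos, frame = frames)[, 2:1]
  out$phi_deg <- NA_real_
  out$d_angstrom <- NA_real_
  for (r in seq_len(nrow(out))) {
    g <- flatness_and_cleft(system, out$frame[r], out$position_n[r])
    out$phi_deg[r] <- g$phi
    out$d_angstrom[r] <- g$d
  }
  out
}

#' Contact-count specification
#'
#' @param selection_a,selection_b Named selections (`"dloop"`,
#'   `"target_cleft"`, `"sd1"`..`"sd4"`, or `"all"`).
#' @param cutoff Distance cutoff, Angstrom (default 10, i.e. the 1 nm
#'   criterion; pairs strictly closer than the cutoff are counted).
#' @param partner_rule `"longitudinal-pointed"`, `"lateral"` or `"explicit"`.
#' @return Object of class `contact_spec`.
#' @export
contact_spec <- function(selection_a = "dloop", selection_b = "all",
                         cutoff = 10,
                         partner_rule = c("longitudinal-pointed", "lateral",
                                          "explicit")) {
  if (cutoff <= 0) stop_config("cutoff must be positive")
  structure(
    list(selection_a = selection_a, selection_b = selection_b,
         cutoff = as.numeric(cutoff), partner_rule = match.arg(partner_rule)),
    class = "contact_spec"
  )
}

#' Count C-alpha contacts between two subunits
#'
#' Number of (a, b) C-alpha pairs with Euclidean distance strictly below the
#' cutoff, a drawn from `selection_a` of the first subunit and b from
#' `selection_b` of the second.
#'
#' @param system A [filament_system()].
#' @param frame Frame index.
#' @param pair Integer pair of subunit positions `c(n_a, n_b)`.
#' @param spec A [contact_spec()].
#' @return Integer count.
#' @export
contact_count <- function(system, frame = 1L, pair, spec = contact_spec()) {
  sa <- get_subunit(system, pair[1])
  sb <- get_subunit(system, pair[2])
  ia <- match(resolve_selection(spec$selection_a, sa$template),
              sa$template$residue_ids)
  ib <- match(resolve_selection(spec$selection_b, sb$template),
              sb$template$residue_ids)
  a <- subunit_coords(system, pair[1], frame)[ia, , drop = FALSE]
  b <- subunit_coords(system, pair[2], frame)[ib, , drop = FALSE]
  count_within(a, b, spec$cutoff)
}

#' D-loop contact profile
#'
#' For each actin position n with a pointed-side longitudinal neighbor
#' (n+2): the number of C-alpha distances below 1 nm between the D-loop of
#' subunit n and the neighbor's C-alpha set, per frame.
#'
#' @param system A [filament_system()] with >= 3 subunits.
#' @param frames Frame indices (default all).
#' @param spec A [contact_spec()] (default: D-loop versus the whole
#'   neighbor, 10 Angstrom cutoff).
#' @return A [contact_profile()].
#' @export
dloop_contact_profile <- function(system, frames = NULL,
                                  spec = contact_spec()) {
  if (n_subunits(system) < 3L) {
    stop_input("D-loop contact profile needs >= 3 subunits")
  }
  frames <- .check_frames(system, frames)
  pos <- positions(system)
  keep <- pos[!is.na(vapply(pos, function(n) {
    neighbor(system, n, "longitudinal-pointed")
  }, 1L))]
  counts <- matrix(0L, length(keep), length(frames))
  for (j in seq_along(keep)) {
    nb <- keep[j] + 2L
    for (f in seq_along(frames)) {
      counts[j, f] <- contact_count(system, frames[f], c(keep[j], nb), spec)
    }
  }
  contact_profile(spec, keep, counts)
}

#' Longitudinal interface integrity
#'
#' Total all-versus-all C-alpha contacts for each longitudinal pair
#' (n, n+2); an interface with zero contacts is flagged as ruptured
#' (protofilament severing).
#'
#' @param system A [filament_system()] with >= 3 subunits.
#' @param frame Frame index.
#' @param cutoff Contact cutoff, Angstrom.
#' @return `data.frame` with columns `barbed`, `pointed`, `n_contacts`,
#'   `ruptured`.
#' @export
interface_integrity <- function(system, frame = 1L, cutoff = 10) {
  if (n_subunits(system) < 3L) {
    stop_input("interface integrity needs >= 3 subunits")
  }
  spec <- contact_spec("all", "all", cutoff = cutoff,
                       partner_rule = "longitudinal-pointed")
  pos <- positions(system)
  keep <- pos[(pos + 2L) %in% pos]
  counts <- vapply(keep, function(n) {
    contact_count(system, frame, c(n, n + 2L), spec)
  }, 1L)
  data.frame(barbed = keep, pointed = keep + 2L, n_contacts = counts,
             ruptured = counts == 0L)
}

#' RMSD series against a reference
#'
#' Per frame, the pooled C-alpha coordinates of the selected subunit
#' positions are rigid-body superposed onto the reference selection and the
#' post-fit RMSD is reported.
#'
#' @param system A [filament_system()].
#' @param selection Integer vector of subunit positions (non-empty).
#' @param reference A frame index of `system`, or an external
#'   [filament_system()] covering the same positions (its first frame is
#'   used).
#' @return Object of class `rmsd_series`: `data.frame` with columns `frame`,
#'   `rmsd_angstrom`.
#' @export
rmsd_series <- function(system, selection, reference = 1L) {
  if (length(selection) == 0L) stop_input("selection must be non-empty")
  pos <- positions(system)
  if (!all(selection %in% pos)) {
    stop_input("selection references positions absent from the system")
  }
  pool <- function(sys, frame) {
    do.call(rbind, lapply(selection, function(n) {
      subunit_coords(sys, n, frame)
    }))
  }
  ref_xyz <- if (inherits(reference, "filament_system")) {
    if (!all(selection %in% positions(reference))) {
      stop_input("reference does not cover the selection")
    }
    pool(reference, 1L)
  } else {
    pool(system, as.integer(reference))
  }
  rmsd <- vapply(seq_len(system$n_frames), function(f) {
    superpose(pool(system, f), ref_xyz)$rmsd_after
  }, 1)
  structure(
    data.frame(frame = seq_len(system$n_frames), rmsd_angstrom = rmsd),
    class = c("rmsd_series", "data.frame")
  )
}
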