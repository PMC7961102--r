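# Boundary-model construction: splicing bare and cofilactin filaments into
# slow- and fast-severing boundary models, longitudinal replication of a
# periodic repeat, and computational cofilin ablation.

## Frame-1 coordinates of a subunit entry.
.frame1 <- function(entry) entry$xyz[, , 1L, drop = TRUE]

#' Splice a bare/cofilactin severing boundary
#'
#' Joins a bare-actin filament and a cofilactin filament end to end into an
#' 18-subunit boundary model with 8 cofilins, relabelled to positions
#' -8..9 with interfacial index i = 0 (cofilactin occupies the side carrying
#' the cluster; position index increases toward the pointed end).
#'
#' Modes:
#' \describe{
#'   \item{slow}{Bare on the barbed side. Cofilactin subunit i is rigid-body
#'     superposed (full-subunit C-alpha) onto bare subunit i; bare i-8..i-1
#'     and cofilactin i..i+9 are kept, with the 8 cofilins whose bridged
#'     pairs lie wholly inside the kept cofilactin segment. The interfacial
#'     actin starts cofilactin-like.}
#'   \item{fast}{Bare on the pointed side. The pooled SD3+SD4 C-alpha of
#'     four subunits spanning i..i+3 from each input are superposed;
#'     cofilactin i-8..i+1 with its 8 interior cofilins and bare i+2..i+9
#'     are kept. The output is flagged `requires_relaxation`: this
#'     construction starts with little to no D-loop contact.}
#'   \item{fast_alt}{The alternative fast construction (interfacial actin
#'     starts actin-like): cofilactin i-8..i-1 plus bare i..i+9, aligned on
#'     subunit i. Provided for completeness.}
#' }
#'
#' Multi-frame inputs are spliced on their first frame.
#'
#' @param bare A [filament_system()] without cofilins (>= 10 subunits).
#' @param cofilactin A [filament_system()] carrying cofilin occupancy
#'   (>= 10 subunits; >= 12 for `mode = "fast"`).
#' @param mode `"slow"`, `"fast"` or `"fast_alt"`.
#' @return A [filament_system()] with `interfacial_index = 0` and a
#'   [boundary_spec()] in `$boundary`.
#' @export
splice_boundary <- function(bare, cofilactin,
                            mode = c("slow", "fast", "fast_alt")) {
  mode <- match.arg(mode)
  if (n_subunits(bare) < 10L || n_subunits(cofilactin) < 10L) {
    stop_topology("splice_boundary requires at least 10 subunits in each input filament")
  }
  if (mode == "fast" && n_subunits(cofilactin) < 12L) {
    stop_topology("fast-mode splicing requires at least 12 cofilactin subunits")
  }
  if (n_cofilins(cofilactin) == 0L) {
    stop_topology("cofilactin input carries no cofilin occupancy")
  }

  bp <- positions(bare)
  cp <- positions(cofilactin)
  sub_xyz <- function(sys, p) .frame1(get_subunit(sys, p))
  core_xyz <- function(sys, p) {
    s <- get_subunit(sys, p)
    core <- c(resolve_selection("sd3", s$template),
              resolve_selection("sd4", s$template))
    .frame1(s)[match(core, s$template$residue_ids), , drop = FALSE]
  }
  take <- function(sys, p, new_pos, tf = NULL) {
    s <- get_subunit(sys, p)
    xyz <- .frame1(s)
    if (!is.null(tf)) xyz <- apply_transform(xyz, tf)
    make_subunit_entry(new_pos, s$template, xyz)
  }
  take_cofilins <- function(sys, kept_keys, shift, tf = NULL) {
    lapply(Filter(function(r) r$key %in% kept_keys, sys$occupancy),
           function(r) {
             xyz <- r$xyz[, , 1L, drop = TRUE]
             if (!is.null(tf)) xyz <- apply_transform(xyz, tf)
             make_cofilin_record(r$key + shift, r$template, xyz)
           })
  }
  ckeys <- cofilin_keys(cofilactin)

  if (mode == "slow") {
    bsel <- utils::tail(bp, 9L)       # bare i-8..i (pointed-most)
    csel <- utils::head(cp, 10L)      # cofilactin i..i+9 (barbed-most)
    tf <- superpose(sub_xyz(cofilactin, csel[1]), sub_xyz(bare, bsel[9]))
    subs <- c(
      lapply(1:8, function(j) take(bare, bsel[j], j - 9L)),
      lapply(1:10, function(j) take(cofilactin, csel[j], j - 1L, tf))
    )
    kept <- ckeys[ckeys %in% csel & (ckeys + 2L) %in% csel]
    cofs <- take_cofilins(cofilactin, kept, -csel[1], tf)
    requires_relax <- FALSE
  } else if (mode == "fast") {
    csel <- utils::tail(cp, 12L)      # cofilactin i-8..i+3 (pointed-most)
    bsel <- utils::head(bp, 10L)      # bare i..i+9 (barbed-most)
    ref <- do.call(rbind, lapply(csel[9:12], function(p) {
      core_xyz(cofilactin, p)
    }))
    mob <- do.call(rbind, lapply(bsel[1:4], function(p) core_xyz(bare, p)))
    tf <- superpose(mob, ref)
    subs <- c(
      lapply(1:10, function(j) take(cofilactin, csel[j], j - 9L)),
      lapply(3:10, function(j) take(bare, bsel[j], j - 3L + 2L, tf))
    )
    kept_segment <- csel[1:10]
    kept <- ckeys[ckeys %in% kept_segment & (ckeys + 2L) %in% kept_segment]
    cofs <- take_cofilins(cofilactin, kept, -csel[9])
    requires_relax <- TRUE
  } else { # fast_alt
    csel <- utils::tail(cp, 9L)       # cofilactin i-8..i
    bsel <- utils::head(bp, 10L)      # bare i..i+9
    tf <- superpose(sub_xyz(bare, bsel[1]), sub_xyz(cofilactin, csel[9]))
    subs <- c(
      lapply(1:8, function(j) take(cofilactin, csel[j], j - 9L)),
      lapply(1:10, function(j) take(bare, bsel[j], j - 1L, tf))
    )
    kept_segment <- csel[1:8]
    kept <- ckeys[ckeys %in% kept_segment & (ckeys + 2L) %in% kept_segment]
    cofs <- take_cofilins(cofilactin, kept, -csel[9])
    requires_relax <- FALSE
  }

  spec <- boundary_spec(
    mode = mode,
    bare_count = if (mode == "slow") 8L else if (mode == "fast") 8L else 10L,
    cofilactin_count = 18L - (if (mode == "fast_alt") 10L else 8L),
    cofilin_count = length(cofs),
    interfacial_index = 0L,
    requires_relaxation = requires_relax
  )
  filament_system(subs, cofs, periodic = FALSE, interfacial_index = 0L,
                  boundary = spec)
}

#' Replicate a periodic filament longitudinally
#'
#' Derives the per-subunit step transform from the filament itself
#' (superposing consecutive subunits), verifies that every adjacent pair is
#' related by that same transform to within `tol` (junction periodicity),
#' and appends `times` transformed copies at the pointed end. Occupancy is
#' replicated with keys shifted by the repeat length; a pointed-end cofilin
#' that bridged into the next periodic image gains its partner in the
#' appended copy, so an 11-subunit / 10-cofilin repeat replicated once
#' yields 22 subunits and 20 cofilins.
#'
#' @param system A periodic-template [filament_system()] with >= 2 subunits,
#'   all sharing one residue numbering.
#' @param times Number of copies to append (`0` returns the input).
#' @param tol Junction periodicity tolerance, Angstrom RMSD (default 0.5).
#' @return A [filament_system()].
#' @export
replicate_longitudinal <- function(system, times = 1L, tol = 0.5) {
  times <- as.integer(times)
  if (times < 0L) stop_input("times must be >= 0")
  if (times == 0L) return(system)
  P <- n_subunits(system)
  if (P < 2L) stop_topology("replication needs >= 2 subunits")
  ids <- lapply(system$subunits, function(s) s$template$residue_ids)
  if (!all(vapply(ids, identical, TRUE, y = ids[[1]]))) {
    stop_topology("replication requires a uniform subunit residue numbering")
  }

  step <- superpose(.frame1(system$subunits[[1]]),
                    .frame1(system$subunits[[2]]))
  for (j in seq_len(P - 1L)) {
    pred <- apply_transform(.frame1(system$subunits[[j]]), step)
    if (rmsd_raw(pred, .frame1(system$subunits[[j + 1L]])) > tol) {
      stop_topology(sprintf(
        "non-periodic input: junction RMSD above %.2f A at pair (%d, %d)",
        tol, positions(system)[j], positions(system)[j + 1L]
      ))
    }
  }

  ## Repeat transform = step composed P times; then powers per copy.
  repeat_tf <- step
  for (j in seq_len(P - 1L)) repeat_tf <- compose_transform(step, repeat_tf)
  copy_tf <- vector("list", times)
  copy_tf[[1]] <- repeat_tf
  if (times > 1L) {
    for (c in 2:times) {
      copy_tf[[c]] <- compose_transform(repeat_tf, copy_tf[[c - 1L]])
    }
  }

  transform_arr <- function(xyz, tf) {
    out <- xyz
    for (f in seq_len(dim(xyz)[3])) {
      out[, , f] <- apply_transform(xyz[, , f, drop = TRUE], tf)
    }
    out
  }
  subs <- system$subunits
  cofs <- system$occupancy
  for (c in seq_len(times)) {
    subs <- c(subs, lapply(system$subunits, function(s) {
      make_subunit_entry(s$position + c * P, s$template,
                         transform_arr(s$xyz, copy_tf[[c]]))
    }))
    cofs <- c(cofs, lapply(system$occupancy, function(r) {
      make_cofilin_record(r$key + c * P, r$template,
                          transform_arr(r$xyz, copy_tf[[c]]))
    }))
  }
  filament_system(subs, cofs, periodic = system$periodic,
                  interfacial_index = system$interfacial_index)
}

#' Computational cofilin ablation
#'
#' Removes bound cofilins from a cofilactin model, leaving all actin
#' coordinates untouched. Cluster layouts are expressed through the keep
#' set: two cofilins arranged longitudinally are keys \{k, k+2\}, two
#' arranged laterally \{k, k+1\}.
#'
#' @param system A [filament_system()] with cofilin occupancy.
#' @param keep Integer vector of cofilin keys to retain (may be empty).
#' @return A [filament_system()] with occupancy reduced to `keep`.
#' @export
ablate_cofilins <- function(system, keep = integer(0)) {
  keep <- as.integer(keep)
  keys <- cofilin_keys(system)
  if (!all(keep %in% keys)) {
    stop_topology("keep references cofilins absent from the system")
  }
  system$occupancy <- Filter(function(r) r$key %in% keep, system$occupancy)
  system
}

#' Contiguous cofilin clusters
#'
#' Groups the bound cofilins into contiguous clusters: two cofilins are
#' contiguous when their keys differ by 1 (lateral neighbors) or 2
#' (longitudinal neighbors).
#'
#' @param system A [filament_system()].
#' @return List of sorted integer key vectors, one per cluster.
#' @export
cofilin_clusters <- function(system) {
  keys <- sort(cofilin_keys(system))
  if (length(keys) == 0L) return(list())
  brk <- c(0L, which(diff(keys) > 2L), length(keys))
  lapply(seq_len(length(brk) - 1L), function(j) {
    keys[(brk[j] + 1L):brk[j + 1L]]
  })
}
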