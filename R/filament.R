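#' Single-subunit template
#'
#' A subunit is represented at the C-alpha level: one coordinate per residue.
#' Actin templates carry the full set of [residue_selections()]; cofilin
#' placeholders do not.
#'
#' @param ca_coords Numeric matrix (n residues x 3), Angstrom.
#' @param kind `"actin"` or `"cofilin"`.
#' @param conformation_label Free label, e.g. `"bare"`, `"cofilactin"`,
#'   `"custom"`.
#' @param residue_ids Ordered 1-based residue indices (default `1:n`).
#' @param selections A [residue_selections()] object (required for actin).
#' @return Object of class `subunit_template`.
#' @export
subunit_template <- function(ca_coords,
                             kind = c("actin", "cofilin"),
                             conformation_label = "custom",
                             residue_ids = seq_len(nrow(ca_coords)),
                             selections = NULL) {
  kind <- match.arg(kind)
  ca_coords <- as.matrix(ca_coords)
  if (ncol(ca_coords) != 3L) stop_input("ca_coords must have 3 columns")
  if (!all(is.finite(ca_coords))) stop_input("ca_coords must be finite")
  residue_ids <- as.integer(residue_ids)
  if (length(residue_ids) != nrow(ca_coords)) {
    stop_input("need exactly one coordinate per residue")
  }
  if (kind == "actin") {
    if (is.null(selections)) selections <- residue_selections()
    covered <- unlist(selections[c("sd1", "sd2", "sd3", "sd4")],
                      use.names = FALSE)
    if (!all(covered %in% residue_ids)) {
      stop_structural("actin template does not cover its subdomain selections")
    }
  }
  structure(
    list(
      residue_ids = residue_ids,
      ca_coords = ca_coords,
      kind = kind,
      conformation_label = conformation_label,
      selections = selections
    ),
    class = "subunit_template"
  )
}

#' @export
print.subunit_template <- function(x, ...) {
  cat(sprintf("<subunit_template> %s (%s), %d residues\n",
              x$kind, x$conformation_label, length(x$residue_ids)))
  invisible(x)
}

## Internal constructor for one positional subunit entry.
make_subunit_entry <- function(position, template, xyz) {
  if (length(dim(xyz)) == 2L) xyz <- array(xyz, dim = c(dim(xyz), 1L))
  stopifnot(dim(xyz)[1] == nrow(template$ca_coords), dim(xyz)[2] == 3L)
  list(position = as.integer(position), template = template, xyz = xyz)
}

## Internal constructor for one cofilin occupancy record. `key` is the
## barbed-side actin of the bridged pair (key, key + 2).
make_cofilin_record <- function(key, template, xyz) {
  if (length(dim(xyz)) == 2L) xyz <- array(xyz, dim = c(dim(xyz), 1L))
  list(key = as.integer(key), pair = as.integer(c(key, key + 2L)),
       template = template, xyz = xyz)
}

#' Filament system
#'
#' The central container: an ordered, polarity-aware set of actin subunits
#' (position index increasing toward the pointed end) plus cofilin occupancy
#' records, each bridging the longitudinal pair (k, k+2) and keyed by its
#' barbed-side actin k, carrying one or more coordinate frames.
#'
#' In a `periodic` system (a repeat of an effectively infinite filament) the
#' pointed-most cofilins may "dangle": their partner k+2 lies in the next
#' periodic image. Non-periodic systems require both bridged actins present.
#'
#' @param subunits List of entries created by the generator/builders; each
#'   holds `position`, `template` and an `xyz` array (residues x 3 x frames).
#' @param occupancy List of cofilin records (`key`, `pair`, `template`, `xyz`).
#' @param periodic Logical; permits dangling pointed-end cofilins.
#' @param interfacial_index Optional position i of the boundary.
#' @param boundary Optional [boundary_spec()].
#' @return Object of class `filament_system`.
#' @export
filament_system <- function(subunits, occupancy = list(), periodic = FALSE,
                            interfacial_index = NULL, boundary = NULL) {
  if (length(subunits) == 0L) stop_topology("a filament needs >= 1 subunit")
  pos <- vapply(subunits, function(s) s$position, 1L)
  o <- order(pos)
  subunits <- subunits[o]
  pos <- pos[o]
  if (length(pos) > 1L && !all(diff(pos) == 1L)) {
    stop_topology("subunit position indices must be consecutive integers")
  }
  nf <- unique(vapply(subunits, function(s) dim(s$xyz)[3], 1L))
  if (length(occupancy)) {
    nf <- unique(c(nf, vapply(occupancy, function(s) dim(s$xyz)[3], 1L)))
  }
  if (length(nf) != 1L) {
    stop_format("all subunits must carry the same number of frames")
  }
  for (rec in occupancy) {
    if (!rec$pair[1] %in% pos) {
      stop_topology(sprintf("cofilin %d: barbed-side actin absent", rec$key))
    }
    if (!rec$pair[2] %in% pos && !periodic) {
      stop_topology(sprintf(
        "cofilin %d bridges (%d, %d) but subunit %d is absent",
        rec$key, rec$pair[1], rec$pair[2], rec$pair[2]
      ))
    }
  }
  keys <- vapply(occupancy, function(r) r$key, 1L)
  if (anyDuplicated(keys)) stop_topology("duplicate cofilin occupancy keys")
  occupancy <- occupancy[order(keys)]
  structure(
    list(
      subunits = subunits,
      occupancy = occupancy,
      n_frames = nf,
      periodic = periodic,
      interfacial_index = interfacial_index,
      boundary = boundary
    ),
    class = "filament_system"
  )
}

#' @export
print.filament_system <- function(x, ...) {
  cat(sprintf(
    "<filament_system> %d actin subunits (positions %d..%d), %d cofilins, %d frame(s)%s\n",
    n_subunits(x), min(positions(x)), max(positions(x)),
    n_cofilins(x), x$n_frames, if (x$periodic) ", periodic" else ""
  ))
  if (!is.null(x$interfacial_index)) {
    cat(sprintf("  interfacial index i = %d\n", x$interfacial_index))
  }
  invisible(x)
}

#' @rdname filament_system
#' @param system A `filament_system`.
#' @export
positions <- function(system) {
  vapply(system$subunits, function(s) s$position, 1L)
}

#' @rdname filament_system
#' @export
n_subunits <- function(system) length(system$subunits)

#' @rdname filament_system
#' @export
n_cofilins <- function(system) length(system$occupancy)

#' @rdname filament_system
#' @export
cofilin_keys <- function(system) {
  vapply(system$occupancy, function(r) r$key, 1L)
}

## Internal: fetch the subunit entry at a position index.
get_subunit <- function(system, n) {
  hit <- which(positions(system) == n)
  if (length(hit) != 1L) {
    stop_topology(sprintf("no subunit at position %d", n))
  }
  system$subunits[[hit]]
}

## Internal: coordinates of subunit n in one frame (matrix n_res x 3).
subunit_coords <- function(system, n, frame = 1L) {
  s <- get_subunit(system, n)
  if (frame < 1L || frame > dim(s$xyz)[3]) {
    stop_input(sprintf("frame %d out of range", frame))
  }
  s$xyz[, , frame, drop = TRUE]
}

#' Conformation label of the subunit at a position
#'
#' @param system A [filament_system()].
#' @param n Position index.
#' @return The template's `conformation_label` string.
#' @export
get_subunit_label <- function(system, n) {
  get_subunit(system, n)$template$conformation_label
}

#' Neighbor of a subunit under the filament topology
#'
#' Consecutive position indices follow the genetic helix, so longitudinal
#' (same protofilament) neighbors differ by 2 and lateral neighbors by 1.
#'
#' @param system A [filament_system()].
#' @param n Position index present in the system.
#' @param rule `"longitudinal-pointed"` (n+2), `"longitudinal-barbed"` (n-2),
#'   or `"lateral"` (n+1).
#' @return The neighbor's position index, or `NA` if it falls outside the
#'   system.
#' @export
neighbor <- function(system, n,
                     rule = c("longitudinal-pointed", "longitudinal-barbed",
                              "lateral")) {
  if (!is.character(rule) ||
      !all(rule %in% c("longitudinal-pointed", "longitudinal-barbed",
                       "lateral"))) {
    stop_config("invalid neighbor rule")
  }
  rule <- match.arg(rule)
  n <- as.integer(n)
  pos <- positions(system)
  if (!n %in% pos) stop_input(sprintf("no subunit at position %d", n))
  m <- switch(rule,
    "longitudinal-pointed" = n + 2L,
    "longitudinal-barbed" = n - 2L,
    "lateral" = n + 1L
  )
  if (m %in% pos) m else NA_integer_
}

#' Boundary specification
#'
#' Records how a spliced boundary model was assembled: which side of the
#' cofilin cluster is bare (`slow` = bare on the barbed side, `fast` = bare
#' on the pointed side), the subunit and cofilin counts, and the interfacial
#' index i.
#'
#' @param mode `"slow"`, `"fast"` or `"fast_alt"`.
#' @param bare_count,cofilactin_count,cofilin_count Subunit/cofilin counts.
#' @param interfacial_index Position i of the barbed-most interfacial actin.
#' @param requires_relaxation Logical; fast-mode splices start with little to
#'   no D-loop contact and are flagged as needing relaxation downstream.
#' @return Object of class `boundary_spec`.
#' @export
boundary_spec <- function(mode, bare_count, cofilactin_count, cofilin_count,
                          interfacial_index, requires_relaxation = FALSE) {
  if (is.null(mode) || is.na(mode) ||
      !mode %in% c("slow", "fast", "fast_alt")) {
    stop_config("boundary mode must be 'slow', 'fast' or 'fast_alt'")
  }
  structure(
    list(
      mode = mode,
      bare_count = as.integer(bare_count),
      cofilactin_count = as.integer(cofilactin_count),
      cofilin_count = as.integer(cofilin_count),
      interfacial_index = as.integer(interfacial_index),
      requires_relaxation = requires_relaxation
    ),
    class = "boundary_spec"
  )
}

#' Putative severing interface of a boundary model
#'
#' The most likely severing location sits where bare actin-like subunits
#' contact the interfacial subunits: at the barbed end of the interfacial
#' actins for the slow boundary (pairs (i-2, i) and (i-1, i+1)) and at their
#' pointed end for the fast boundary (pairs (i, i+2) and (i+1, i+3)).
#'
#' @param spec A [boundary_spec()].
#' @return Two-row integer matrix; each row is a longitudinal subunit pair.
#' @export
putative_severing_interface <- function(spec) {
  if (!inherits(spec, "boundary_spec")) {
    stop_config("spec must be a boundary_spec")
  }
  i <- spec$interfacial_index
  out <- switch(spec$mode,
    slow = rbind(c(i - 2L, i), c(i - 1L, i + 1L)),
    fast = ,
    fast_alt = rbind(c(i, i + 2L), c(i + 1L, i + 3L))
  )
  dimnames(out) <- list(NULL, c("barbed", "pointed"))
  out
}

#' Cofilins touching a subunit position
#'
#' A cofilin keyed k bridges actins k and k+2; interfacial subunits of a
#' spliced boundary each touch exactly one cofilin.
#'
#' @param system A [filament_system()].
#' @param n Position index.
#' @return Integer vector of occupancy keys whose bridged pair includes `n`.
#' @export
cofilins_touching <- function(system, n) {
  keys <- cofilin_keys(system)
  keys[keys == n | keys == n - 2L]
}
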