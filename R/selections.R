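#' Canonical actin subdomain residue ranges
#'
#' The four-subdomain partition of the 375-residue actin monomer used
#' throughout the package: SD1 = 1-32, 70-137, 338-375; SD2 = 33-69
#' (containing the D-loop); SD3 = 138-180, 270-337; SD4 = 181-269.
#' All ranges are configurable via [residue_selections()]; this function
#' only supplies the defaults.
#'
#' @return Named list of integer vectors `sd1`..`sd4`.
#' @export
actin_subdomains <- function() {
  list(
    sd1 = c(1:32, 70:137, 338:375),
    sd2 = 33:69,
    sd3 = c(138:180, 270:337),
    sd4 = 181:269
  )
}

#' Residue selections for an actin subunit
#'
#' Bundles the named residue-index sets the analyses rely on: the D-loop
#' (DNase-I binding loop, default residues 44-52), the target binding cleft
#' of the pointed-end neighbor (default 143-148 and 349-351), and the four
#' subdomains. Indices are 1-based and inclusive.
#'
#' @param dloop Integer vector of D-loop residues. Must lie inside `sd2`.
#' @param target_cleft Integer vector of target-binding-cleft residues.
#' @param subdomains Named list `sd1`..`sd4` of mutually disjoint integer
#'   vectors whose union covers the subunit residue range without gaps.
#' @return Object of class `residue_selections`.
#' @export
residue_selections <- function(dloop = 44:52,
                               target_cleft = c(143:148, 349:351),
                               subdomains = actin_subdomains()) {
  dloop <- sort(unique(as.integer(dloop)))
  target_cleft <- sort(unique(as.integer(target_cleft)))
  need <- c("sd1", "sd2", "sd3", "sd4")
  if (!all(need %in% names(subdomains))) {
    stop_config("subdomains must name sd1, sd2, sd3 and sd4")
  }
  sds <- lapply(subdomains[need], function(x) sort(unique(as.integer(x))))
  all_res <- unlist(sds, use.names = FALSE)
  if (length(dloop) == 0L || length(target_cleft) == 0L ||
      any(vapply(sds, length, 1L) == 0L)) {
    stop_config("all residue selections must be non-empty")
  }
  if (anyDuplicated(all_res)) {
    stop_config("subdomains sd1..sd4 must be mutually disjoint")
  }
  if (!setequal(all_res, seq_len(max(all_res)))) {
    stop_config("subdomains must cover the full residue range without gaps")
  }
  if (!all(dloop %in% sds$sd2)) {
    stop_config("dloop residues must lie within subdomain 2")
  }
  if (!all(target_cleft %in% all_res)) {
    stop_config("target_cleft residues must lie within the subunit range")
  }
  structure(
    c(list(dloop = dloop, target_cleft = target_cleft), sds),
    class = "residue_selections"
  )
}

#' Resolve a named residue selection on a subunit
#'
#' @param name One of `"dloop"`, `"target_cleft"`, `"sd1"`..`"sd4"`, or
#'   `"all"` (every residue of the subunit).
#' @param subunit A [subunit_template()].
#' @return Sorted integer vector of 1-based residue indices.
#' @export
resolve_selection <- function(name, subunit) {
  stopifnot(inherits(subunit, "subunit_template"))
  if (identical(name, "all")) {
    return(subunit$residue_ids)
  }
  sel <- subunit$selections
  if (is.null(sel)) {
    stop_structural(sprintf(
      "selection '%s' requested on a %s subunit that carries no selections",
      name, subunit$kind
    ))
  }
  if (!name %in% names(sel)) {
    stop_config(sprintf("unknown selection name '%s'", name))
  }
  idx <- sel[[name]]
  if (!all(idx %in% subunit$residue_ids)) {
    stop_structural(sprintf(
      "selection '%s' references residues absent from the subunit", name
    ))
  }
  sort(unique(as.integer(idx)))
}
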