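# PDB input/output. Filaments are written as C-alpha-only fixed-width PDB
# (one chain per subunit, one MODEL per frame) and read back either through
# an explicit chain map or by automatic chain classification.

.chain_pool <- function() c(LETTERS, letters, as.character(0:9))

#' Chain map of a filament system
#'
#' Chain IDs are drawn from A-Z, a-z, 0-9: actin subunits first in position
#' order, then cofilins in key order (for cofilins, `position` is the
#' occupancy key).
#'
#' @param system A [filament_system()].
#' @return `data.frame` with columns `chain`, `position`, `kind`.
#' @export
system_chain_map <- function(system) {
  n_chains <- n_subunits(system) + n_cofilins(system)
  pool <- .chain_pool()
  if (n_chains > length(pool)) {
    stop_format(sprintf(
      "%d chains exceed the %d available PDB chain IDs; split the output",
      n_chains, length(pool)
    ))
  }
  data.frame(
    chain = pool[seq_len(n_chains)],
    position = c(positions(system), cofilin_keys(system)),
    kind = c(rep("actin", n_subunits(system)),
             rep("cofilin", n_cofilins(system))),
    stringsAsFactors = FALSE
  )
}

#' Write a filament system as a PDB file
#'
#' Fixed-width ATOM records (CA atoms only, occupancy 1.00, B-factor 0.00),
#' one chain per subunit with TER after each chain, frames as MODEL/ENDMDL
#' blocks (omitted for a single frame).
#'
#' @param system A [filament_system()].
#' @param path Output file path.
#' @return The chain map (see [system_chain_map()]), invisibly.
#' @export
write_system <- function(system, path) {
  if (!inherits(system, "filament_system")) {
    stop_format("write_system needs a filament_system")
  }
  cmap <- system_chain_map(system)
  entries <- c(system$subunits, system$occupancy)
  lines <- character(0)
  multi <- system$n_frames > 1L
  for (f in seq_len(system$n_frames)) {
    if (multi) lines <- c(lines, sprintf("MODEL     %4d", f))
    serial <- 0L
    for (j in seq_along(entries)) {
      ent <- entries[[j]]
      tpl <- ent$template
      xyz <- ent$xyz[, , f, drop = TRUE]
      serials <- serial + seq_len(nrow(xyz))
      lines <- c(lines, sprintf(
        "ATOM  %5d %4s%1s%3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serials, " CA ", " ", "ALA", cmap$chain[j], tpl$residue_ids, " ",
        xyz[, 1], xyz[, 2], xyz[, 3], 1, 0, " C"
      ))
      serial <- serials[length(serials)]
      lines <- c(lines, "TER")
    }
    if (multi) lines <- c(lines, "ENDMDL")
  }
  lines <- c(lines, "END")
  writeLines(lines, path)
  invisible(cmap)
}

#' Read a filament system from a PDB file
#'
#' One frame per MODEL record (single frame if none). With an explicit
#' `chain_map` the subunit positions, kinds and cofilin keys are taken from
#' the map; with `chain_map = NULL` chains are classified automatically:
#' chains with >= 300 residues are actin, < 200 residues cofilin; actin
#' positions are assigned by projecting chain centers onto the filament
#' axis (barbed to pointed = increasing), and each cofilin is keyed to the
#' longitudinal actin pair whose bridging midpoint it sits on.
#'
#' @param path PDB file path (C-alpha coordinates; every residue must have
#'   a CA atom).
#' @param chain_map Optional `data.frame` with columns `chain`, `position`,
#'   `kind` (as returned by [write_system()]).
#' @param selections [residue_selections()] attached to actin chains.
#' @return A [filament_system()].
#' @export
read_system <- function(path, chain_map = NULL,
                        selections = residue_selections()) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) stop_format(sprintf("cannot parse PDB: %s",
                                            conditionMessage(e)))
  )
  at <- pdb$atom
  ca <- which(at$elety == "CA")
  if (length(ca) == 0L) stop_structural("no CA atoms found")
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_frames <- nrow(xyz)

  chains <- unique(at$chain[ca])
  per_chain <- lapply(chains, function(ch) {
    rows <- ca[at$chain[ca] == ch]
    resno <- at$resno[rows]
    if (anyDuplicated(resno)) {
      stop_structural(sprintf("chain %s: duplicated residue numbers", ch))
    }
    full <- seq(min(resno), max(resno))
    miss <- setdiff(full, resno)
    if (length(miss)) {
      stop_structural(sprintf("chain %s: missing CA for residue %d",
                              ch, miss[1]))
    }
    o <- order(resno)
    list(chain = ch, resno = resno[o], rows = rows[o])
  })
  names(per_chain) <- chains

  coords_arr <- function(info) {
    idx <- info$rows
    arr <- array(NA_real_, dim = c(length(idx), 3L, n_frames))
    for (f in seq_len(n_frames)) {
      m <- matrix(xyz[f, ], ncol = 3, byrow = TRUE)
      arr[, , f] <- m[idx, , drop = FALSE]
    }
    if (!all(is.finite(arr))) {
      stop_format(sprintf("chain %s: inconsistent models", info$chain))
    }
    arr
  }

  if (is.null(chain_map)) {
    n_res <- vapply(per_chain, function(x) length(x$resno), 1L)
    kind <- ifelse(n_res >= 300L, "actin",
                   ifelse(n_res < 200L, "cofilin", NA))
    if (anyNA(kind)) {
      stop_format("chain with 200-299 residues cannot be classified; supply a chain_map")
    }
    actin_ch <- chains[kind == "actin"]
    cof_ch <- chains[kind == "cofilin"]
    if (length(actin_ch) == 0L) stop_format("no actin chains found")
    com1 <- t(vapply(per_chain[actin_ch], function(info) {
      colMeans(matrix(xyz[1, ], ncol = 3, byrow = TRUE)[info$rows, ,
                                                        drop = FALSE])
    }, numeric(3)))
    ctr <- colMeans(com1)
    ax <- svd(sweep(com1, 2, ctr))$v[, 1]
    proj <- as.numeric(sweep(com1, 2, ctr) %*% ax)
    if (length(proj) > 1L &&
        stats::cor(proj, seq_along(proj)) < 0) {
      proj <- -proj  # orient the axis along the file's chain order
    }
    pos <- rank(proj, ties.method = "first")
    chain_map <- data.frame(
      chain = c(actin_ch, cof_ch),
      position = c(as.integer(pos), rep(NA_integer_, length(cof_ch))),
      kind = c(rep("actin", length(actin_ch)),
               rep("cofilin", length(cof_ch))),
      stringsAsFactors = FALSE
    )
  } else {
    missing_ch <- setdiff(chains, chain_map$chain)
    if (length(missing_ch)) {
      stop_format(sprintf("chain %s absent from chain_map", missing_ch[1]))
    }
  }

  amap <- chain_map[chain_map$kind == "actin", ]
  subs <- lapply(seq_len(nrow(amap)), function(j) {
    info <- per_chain[[amap$chain[j]]]
    arr <- coords_arr(info)
    tpl <- subunit_template(arr[, , 1, drop = TRUE], kind = "actin",
                            conformation_label = "custom",
                            residue_ids = info$resno,
                            selections = selections)
    make_subunit_entry(amap$position[j], tpl, arr)
  })

  cmapf <- chain_map[chain_map$kind == "cofilin" &
                       chain_map$chain %in% chains, ]
  cofs <- list()
  if (nrow(cmapf)) {
    ## Bridging midpoints of every longitudinal actin pair, frame 1.
    sub_by_pos <- stats::setNames(subs, vapply(subs, `[[`, 1L, "position"))
    apos <- sort(as.integer(names(sub_by_pos)))
    cand <- apos[(apos + 2L) %in% apos]
    mids <- if (length(cand)) t(vapply(cand, function(n) {
      sa <- sub_by_pos[[as.character(n)]]
      sb <- sub_by_pos[[as.character(n + 2L)]]
      (selection_com(sa$template, sa$xyz[, , 1, drop = TRUE], "sd2") +
         selection_com(sb$template, sb$xyz[, , 1, drop = TRUE], "sd1")) / 2
    }, numeric(3))) else NULL
    cofs <- lapply(seq_len(nrow(cmapf)), function(j) {
      info <- per_chain[[cmapf$chain[j]]]
      arr <- coords_arr(info)
      key <- cmapf$position[j]
      if (is.na(key)) {
        if (is.null(mids)) {
          stop_format("cannot infer cofilin keys: no longitudinal actin pairs")
        }
        com <- colMeans(arr[, , 1, drop = TRUE])
        key <- cand[which.min(rowSums(sweep(mids, 2, com)^2))]
      }
      tpl <- subunit_template(arr[, , 1, drop = TRUE], kind = "cofilin",
                              conformation_label = "cofilin",
                              residue_ids = info$resno)
      make_cofilin_record(key, tpl, arr)
    })
  }

  apos <- vapply(subs, `[[`, 1L, "position")
  keys <- vapply(cofs, function(r) r$key, integer(1)) %||% integer(0)
  dangling <- length(cofs) > 0 &&
    any(!(vapply(cofs, function(r) r$pair[2], 1L) %in% apos))
  filament_system(subs, cofs, periodic = dangling)
}
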