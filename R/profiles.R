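#' Per-position angle profile
#'
#' Holds an angular observable (adjacent-subunit twist or flatness angle phi)
#' per subunit position and frame, with per-position mean and population SD
#' over frames.
#'
#' @param observable `"twist"` or `"phi"` (free-form labels allowed).
#' @param positions Integer vector of subunit positions (sorted).
#' @param values Numeric matrix, positions x frames, degrees.
#' @return Object of class `angle_profile`.
#' @export
angle_profile <- function(observable, positions, values) {
  values <- as.matrix(values)
  positions <- as.integer(positions)
  if (nrow(values) != length(positions)) {
    stop_input("values must have one row per position")
  }
  o <- order(positions)
  positions <- positions[o]
  values <- values[o, , drop = FALSE]
  structure(
    list(
      observable = observable,
      positions = positions,
      values = values,
      mean = rowMeans(values),
      sd = apply(values, 1, function(v) sqrt(mean((v - mean(v))^2)))
    ),
    class = "angle_profile"
  )
}

#' @export
print.angle_profile <- function(x, ...) {
  cat(sprintf("<angle_profile> %s, %d positions x %d frame(s)\n",
              x$observable, length(x$positions), ncol(x$values)))
  print(data.frame(position_n = x$positions, mean = x$mean, sd = x$sd),
        row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.angle_profile <- function(x, ...) {
  data.frame(
    frame = rep(seq_len(ncol(x$values)), each = length(x$positions)),
    position_n = rep(x$positions, ncol(x$values)),
    value_deg = as.numeric(x$values)
  )
}

#' Per-position contact-count profile
#'
#' @param spec A [contact_spec()].
#' @param positions Integer vector of subunit positions.
#' @param counts Integer matrix, positions x frames.
#' @return Object of class `contact_profile`.
#' @export
contact_profile <- function(spec, positions, counts) {
  counts <- as.matrix(counts)
  positions <- as.integer(positions)
  if (nrow(counts) != length(positions)) {
    stop_input("counts must have one row per position")
  }
  if (any(counts < 0)) stop_input("contact counts must be non-negative")
  o <- order(positions)
  structure(
    list(
      spec = spec,
      positions = positions[o],
      values = counts[o, , drop = FALSE]
    ),
    class = "contact_profile"
  )
}

#' @export
as.data.frame.contact_profile <- function(x, ...) {
  data.frame(
    frame = rep(seq_len(ncol(x$values)), each = length(x$positions)),
    position_n = rep(x$positions, ncol(x$values)),
    n_contacts = as.integer(x$values)
  )
}

#' Trailing-window per-position statistics
#'
#' Mean and population standard deviation over the trailing `last_k` frames
#' of a profile, mirroring how equilibrium-window statistics are quoted for
#' trajectory observables.
#'
#' @param profile An [angle_profile()] or [contact_profile()].
#' @param last_k Number of trailing frames to use; defaults to half the
#'   frames (rounded up).
#' @return `data.frame` with columns `position_n`, `mean`, `sd`.
#' @export
per_position_stats <- function(profile, last_k = NULL) {
  if (!inherits(profile, c("angle_profile", "contact_profile"))) {
    stop_input("profile must be an angle_profile or contact_profile")
  }
  nf <- ncol(profile$values)
  if (is.null(last_k)) last_k <- ceiling(nf / 2)
  last_k <- as.integer(last_k)
  if (last_k < 1L) stop_config("last_k must be a positive frame count")
  if (last_k > nf) stop_config("last_k exceeds the number of frames")
  v <- profile$values[, seq.int(nf - last_k + 1L, nf), drop = FALSE]
  data.frame(
    position_n = profile$positions,
    mean = rowMeans(v),
    sd = apply(v, 1, function(x) sqrt(mean((x - mean(x))^2)))
  )
}
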