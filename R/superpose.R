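#' Least-squares rigid-body superposition (Kabsch)
#'
#' Finds the proper rotation R and translation t minimising the RMSD between
#' `mobile` transformed by (R, t) and `reference`, using the Kabsch/SVD
#' solution. Points correspond row by row.
#'
#' @param mobile,reference Numeric matrices (n x 3), n >= 3, same n.
#' @return Object of class `rigid_transform`: `rotation` (3x3, column-vector
#'   convention, det = +1), `translation` (length 3), and `rmsd_after`
#'   (Angstrom) of the transformed mobile set versus the reference.
#' @export
superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile)
  reference <- as.matrix(reference)
  if (!identical(dim(mobile), dim(reference))) {
    stop_input("mobile and reference must have identical dimensions")
  }
  if (ncol(mobile) != 3L) stop_input("coordinate sets must be n x 3")
  n <- nrow(mobile)
  if (n < 3L) stop_input("superposition needs at least 3 points")
  cm <- colMeans(mobile)
  cr <- colMeans(reference)
  X <- sweep(mobile, 2, cm)
  Y <- sweep(reference, 2, cr)
  ## Degenerate (collinear or coincident) sets have rank < 2.
  if (qr(X)$rank < 2L || qr(Y)$rank < 2L) {
    stop_numerical("degenerate point set: rigid superposition is ill-posed")
  }
  M <- crossprod(X, Y)                     # t(X) %*% Y
  sv <- svd(M)
  s <- sign(det(sv$u) * det(sv$v))
  A <- sv$u %*% diag(c(1, 1, s)) %*% t(sv$v)  # row convention: x' = x %*% A
  R <- t(A)                                   # column-vector convention
  t_vec <- cr - as.numeric(cm %*% A)
  fitted <- sweep(mobile %*% A, 2, t_vec, `+`)
  rmsd <- sqrt(mean(rowSums((fitted - reference)^2)))
  structure(
    list(rotation = R, translation = t_vec, rmsd_after = rmsd),
    class = "rigid_transform"
  )
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> angle %.3f deg, rmsd_after %.4g A\n",
              rotation_angle(x$rotation), x$rmsd_after))
  invisible(x)
}

#' Apply a rigid transform to coordinates
#'
#' @param xyz Numeric matrix (n x 3).
#' @param transform A `rigid_transform` from [superpose()].
#' @return Transformed n x 3 matrix.
#' @export
apply_transform <- function(xyz, transform) {
  sweep(as.matrix(xyz) %*% t(transform$rotation), 2,
        transform$translation, `+`)
}

## Compose two rigid transforms: apply `first`, then `second`.
compose_transform <- function(second, first) {
  structure(
    list(
      rotation = second$rotation %*% first$rotation,
      translation = as.numeric(second$rotation %*% first$translation) +
        second$translation,
      rmsd_after = NA_real_
    ),
    class = "rigid_transform"
  )
}

## Root-mean-square deviation between two matched coordinate sets (no fit).
rmsd_raw <- function(a, b) sqrt(mean(rowSums((as.matrix(a) - as.matrix(b))^2)))
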