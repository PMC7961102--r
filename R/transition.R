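#' Boundary transition model parameters
#'
#' The sigmoid crossover model for an angular observable across a
#' bare/cofilactin boundary:
#' theta(n) = A2 - (A2 - A1) / (1 + exp((n - n0) / N)),
#' with barbed-side asymptote A1 (n -> -Inf), pointed-side asymptote A2
#' (n -> +Inf), crossover center n0 and crossover length N (subunits).
#'
#' @param A1,A2 Asymptotic angles, degrees.
#' @param n0 Crossover center, subunit position units.
#' @param N Crossover (decay) length, subunits; must be > 0.
#' @return Object of class `transition_params`.
#' @export
transition_params <- function(A1, A2, n0, N) {
  if (!is.finite(N) || N <= 0) stop_domain("crossover length N must be > 0")
  structure(list(A1 = as.numeric(A1), A2 = as.numeric(A2),
                 n0 = as.numeric(n0), N = as.numeric(N)),
            class = "transition_params")
}

#' @export
print.transition_params <- function(x, ...) {
  cat(sprintf("<transition_params> A1 = %.3f, A2 = %.3f, n0 = %.3f, N = %.3f\n",
              x$A1, x$A2, x$n0, x$N))
  invisible(x)
}

#' Evaluate the boundary transition model
#'
#' @param params A [transition_params()].
#' @param n Subunit position(s); real-valued allowed.
#' @return theta(n) in degrees, same length as `n`.
#' @export
evaluate_transition <- function(params, n) {
  if (!inherits(params, "transition_params")) {
    params <- do.call(transition_params, as.list(params)[c("A1", "A2",
                                                           "n0", "N")])
  }
  params$A2 - (params$A2 - params$A1) /
    (1 + exp((n - params$n0) / params$N))
}

#' Fit the boundary transition model to a per-position angle profile
#'
#' Nonlinear least squares (Levenberg-Marquardt, bounded) on the per-position
#' means of the profile. Initialisation: A1 = mean of the 3 most-barbed
#' positions, A2 = mean of the 3 most-pointed, n0 = linearly interpolated
#' position where the means first cross (A1 + A2)/2, N = 1; N is bounded
#' below at 0.05 subunits.
#'
#' @param profile An [angle_profile()] with >= 5 positions.
#' @param weighting `"none"` or `"inverse-variance"` (weights 1/SD^2 of the
#'   per-position frame scatter; positions with zero SD get the largest
#'   finite weight present).
#' @return Object of class `transition_fit` with elements `params`
#'   ([transition_params()]), `rss`, `converged`, and `se` (per-parameter
#'   standard errors, `NA` when unavailable).
#' @export
fit_transition <- function(profile, weighting = c("none",
                                                  "inverse-variance")) {
  weighting <- match.arg(weighting)
  if (!inherits(profile, "angle_profile")) {
    stop_input("profile must be an angle_profile")
  }
  n <- profile$positions
  y <- profile$mean
  ok <- is.finite(y)
  n <- n[ok]
  y <- y[ok]
  if (length(n) < 5L) stop_input("need >= 5 positions with finite means")

  o <- order(n)
  n <- n[o]
  y <- y[o]
  a1 <- mean(y[1:3])
  a2 <- mean(y[(length(y) - 2):length(y)])
  if (abs(a1 - a2) < 0.5) {
    stop_domain("no transition detected: profile is flat (asymptote difference < 0.5 degrees)")
  }
  mid <- (a1 + a2) / 2
  ## First crossing of the midpoint, linearly interpolated.
  s <- sign(y - mid)
  cross <- which(s[-1] != s[-length(s)])[1]
  n0_init <- if (is.na(cross)) mean(range(n)) else {
    n[cross] + (mid - y[cross]) / (y[cross + 1] - y[cross]) *
      (n[cross + 1] - n[cross])
  }

  w <- rep(1, length(n))
  if (weighting == "inverse-variance") {
    sdv <- profile$sd[ok][o]
    v <- sdv^2
    v[v == 0] <- if (any(v > 0)) min(v[v > 0]) else 1
    w <- 1 / v
  }

  dat <- data.frame(n = n, y = y)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ A2 - (A2 - A1) / (1 + exp((n - n0) / N)),
      data = dat,
      start = list(A1 = a1, A2 = a2, n0 = n0_init, N = 1),
      lower = c(A1 = -Inf, A2 = -Inf, n0 = -Inf, N = 0.05),
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                           ptol = 1e-12)
    ),
    error = function(e) NULL
  )
  if (is.null(fit)) {
    return(structure(
      list(params = transition_params(a1, a2, n0_init, 1),
           rss = NA_real_, converged = FALSE,
           se = c(A1 = NA, A2 = NA, n0 = NA, N = NA)),
      class = "transition_fit"
    ))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(A1 = NA, A2 = NA, n0 = NA, N = NA))
  structure(
    list(
      params = transition_params(cf[["A1"]], cf[["A2"]], cf[["n0"]],
                                 cf[["N"]]),
      rss = sum(stats::residuals(fit)^2),
      converged = fit$convInfo$isConv %||% TRUE,
      se = se
    ),
    class = "transition_fit"
  )
}

#' @export
print.transition_fit <- function(x, ...) {
  print(x$params)
  cat(sprintf("  rss = %.4g, converged = %s\n", x$rss, x$converged))
  invisible(x)
}

#' Serialize a transition fit to JSON
#'
#' @param fit A `transition_fit`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_transition_fit <- function(fit, path) {
  jsonlite::write_json(
    list(A1_deg = fit$params$A1, A2_deg = fit$params$A2,
         n0 = fit$params$n0, N = fit$params$N,
         rss = fit$rss, converged = fit$converged),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
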