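composite_parts <- function(fit) {
  if (!inherits(fit, "decay_model_fit") || fit$family != "composite" ||
      !isTRUE(fit$converged)) {
    stop("transition analysis requires a converged composite fit", call. = FALSE)
  }
  co <- fit$coefficients
  list(a = co[["a"]], b = co[["b"]], c = co[["c"]], p = co[["p"]])
}

# f, f', f'' of the composite curve a*exp(-b x) + c*x^p.
composite_derivs <- function(par, x) {
  e <- par$a * exp(-par$b * x)
  f <- e + par$c * x^par$p
  f1 <- -par$b * e + par$c * par$p * x^(par$p - 1)
  f2 <- par$b^2 * e + par$c * par$p * (par$p - 1) * x^(par$p - 2)
  list(f = f, f1 = f1, f2 = f2)
}

#' Curvature of a composite decay curve in log-log space
#'
#' Writes the fitted curve as g(u) = log10 f(10^u) over log10-distance u and
#' evaluates its second derivative on a uniform u-grid spanning
#' [log10(1), log10(D)]. The second derivative is computed by central
#' differences, with an analytic closed form (from symbolic differentiation
#' of g) available as a cross-check via `method = "analytic"`. A power law is
#' affine in log-log space (g'' = 0); the composite curve's g'' dips where
#' the exponential component hands over to the power-law component.
#'
#' @param fit a converged composite `decay_model_fit` with both amplitudes
#'   positive.
#' @param D maximum distance of the fitted domain.
#' @param n_grid number of grid points (default 2000).
#' @param method "central" (default) or "analytic".
#' @return data frame with columns `u` (log10 distance), `x` (distance) and
#'   `g2` (second derivative of g).
#' @export
log_space_curvature <- function(fit, D, n_grid = 2000L,
                                method = c("central", "analytic")) {
  method <- match.arg(method)
  par <- composite_parts(fit)
  if (par$a <= 0 || par$c <= 0) {
    stop("curvature requires both composite amplitudes > 0", call. = FALSE)
  }
  if (D <= 1) stop("domain maximum must exceed 1", call. = FALSE)
  u <- seq(0, log10(D), length.out = n_grid)
  x <- 10^u
  if (any(composite_derivs(par, x)$f <= 0)) {
    stop("fitted curve non-positive on the domain; not log-transformable",
         call. = FALSE)
  }
  g2 <- if (method == "analytic") {
    dv <- composite_derivs(par, x)
    h1 <- (dv$f1 + x * dv$f2) / dv$f - x * (dv$f1 / dv$f)^2
    log(10) * x * h1
  } else {
    # fourth-order central stencil for the second derivative
    h <- u[2L] - u[1L]
    g <- function(uu) log10(composite_derivs(par, 10^uu)$f)
    (-g(u - 2 * h) + 16 * g(u - h) - 30 * g(u) + 16 * g(u + h) -
       g(u + 2 * h)) / (12 * h^2)
  }
  data.frame(u = u, x = x, g2 = g2)
}

#' Exponential-to-power-law transition point of a composite fit
#'
#' The minimand of the log-log second derivative marks where the curve
#' switches from exponential- to power-law-dominated decay; the integer
#' transition distance is the point immediately prior, i.e. the floor of the
#' continuous minimand (ties broken toward the smaller distance;
#' `mode = "nearest"` rounds instead). Under the composite model this is the
#' greatest inter-element distance at which comparisons still tend to fall
#' within one subroutine, so it predicts subroutine length.
#'
#' @param fit a converged composite `decay_model_fit`.
#' @param D maximum distance of the fitted domain (the grid is restricted to
#'   [1, D]).
#' @param n_grid grid resolution (default 2000).
#' @param mode integer mapping: "floor" (default) or "nearest".
#' @return an object of class `transition_point`: list with
#'   `transition_distance` (integer), `continuous_distance`, `curvature`
#'   (the grid data frame), `boundary` (TRUE when the minimand sits on the
#'   grid edge, flagging an unreliable estimate).
#' @export
transition_point <- function(fit, D, n_grid = 2000L,
                             mode = c("floor", "nearest")) {
  mode <- match.arg(mode)
  curv <- log_space_curvature(fit, D, n_grid)
  i <- which.min(curv$g2)  # which.min takes the first, i.e. smaller distance
  boundary <- i == 1L || i == nrow(curv)
  if (boundary) {
    warning("curvature minimand on the grid boundary; transition unreliable")
  }
  xc <- curv$x[i]
  td <- if (mode == "floor") max(1L, as.integer(floor(xc))) else
    max(1L, as.integer(round(xc)))
  structure(
    list(transition_distance = td, continuous_distance = xc,
         curvature = curv, boundary = boundary),
    class = "transition_point"
  )
}

#' @export
print.transition_point <- function(x, ...) {
  cat("<transition_point>", x$transition_distance,
      "(continuous", format(x$continuous_distance, digits = 4), ")",
      if (x$boundary) "[boundary: unreliable]", "\n")
  invisible(x)
}

#' Compare a transition point with per-nut sequence length
#'
#' Composite decay could in principle arise from mere concatenation of
#' per-nut action sequences; this check asks whether the transition distance
#' is substantially shorter than the mean number of actions used to crack a
#' single nut. "Shorter" is operationalized as transition < mean - 2 SE; the
#' flag is raised when that fails.
#'
#' @param transition a `transition_point`.
#' @param summary a `corpus_summary` with per-nut statistics.
#' @return one-row data frame: `transition`, `per_nut_mean`, `per_nut_se`,
#'   `margin` ((mean - transition)/SE), `flag` (TRUE when the transition is
#'   not clearly shorter), `available`.
#' @export
compare_to_per_nut_length <- function(transition, summary) {
  stopifnot(inherits(transition, "transition_point"))
  m <- summary$mean_per_nut_length[1L]
  se <- summary$se_per_nut_length[1L]
  td <- transition$transition_distance
  if (is.na(m) || is.na(se)) {
    message("per-nut statistics unavailable; comparison skipped")
    return(data.frame(transition = td, per_nut_mean = NA_real_,
                      per_nut_se = NA_real_, margin = NA_real_,
                      flag = NA, available = FALSE))
  }
  data.frame(transition = td, per_nut_mean = m, per_nut_se = se,
             margin = (m - td) / se, flag = td >= m - 2 * se,
             available = TRUE)
}
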