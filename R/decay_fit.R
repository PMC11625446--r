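decay_families <- c("exponential", "power_law", "composite")

decay_formula <- function(family) {
  switch(family,
         exponential = mi_adj ~ a * exp(-d * b),
         power_law = mi_adj ~ a * d^b,
         composite = mi_adj ~ a * exp(-d * b) + c * d^p)
}

#' Evaluate a fitted decay model
#'
#' @param fit a `decay_model_fit`.
#' @param x numeric vector of distances (>= 1 for the power-law component).
#' @return predicted MI values.
#' @export
predict_decay <- function(fit, x) {
  co <- fit$coefficients
  switch(fit$family,
         exponential = co[["a"]] * exp(-x * co[["b"]]),
         power_law = co[["a"]] * x^co[["b"]],
         composite = co[["a"]] * exp(-x * co[["b"]]) + co[["c"]] * x^co[["p"]])
}

# Deterministic multi-start grids; the data-dependent amplitude uses the
# largest observed MI value. No constant term: irreducible aperiodic Markov
# sources imply decay towards zero, so all families are fitted without an
# additive offset.
start_grid <- function(family, mi_adj) {
  amp <- unique(c(0.1, 1, max(max(mi_adj), 1e-3)))
  rates <- c(0.05, 0.3, 1.0)
  powers <- c(-0.1, -0.5, -1.5)
  switch(family,
         exponential = expand.grid(a = amp, b = rates),
         power_law = expand.grid(a = amp, b = powers),
         composite = expand.grid(a = amp, b = rates, c = amp, p = powers))
}

fit_bounds <- function(family) {
  switch(family,
         exponential = list(lower = c(a = 0, b = 0),
                            upper = c(a = Inf, b = Inf)),
         power_law = list(lower = c(a = 0, b = -Inf),
                          upper = c(a = Inf, b = 0)),
         composite = list(lower = c(a = 0, b = 0, c = 0, p = -Inf),
                          upper = c(a = Inf, b = Inf, c = Inf, p = 0)))
}

#' Fit one decay model family to adjusted MI data
#'
#' Least-squares fit in linear space by the Levenberg-Marquardt algorithm
#' (via [minpack.lm::nlsLM()]), with no additive constant. The three
#' families are a*exp(-x*b) (exponential; Markovian, adjacent dependencies),
#' a*x^b with b <= 0 (power law; fully nested hierarchy), and
#' a*exp(-x*b) + c*x^d (composite; Markov subroutines arranged
#' hierarchically). A deterministic grid of starting values is tried and the
#' best-RSS converged solution returned; amplitudes are bounded below by 0,
#' exponential rates are >= 0 and power exponents <= 0 so every fitted curve
#' decays towards zero. Negative MI values near the noise floor are
#' permitted and retained.
#'
#' @param points data frame with columns `d` (distances >= 1) and `mi_adj`,
#'   or a `mi_decay_curve` (rows with d >= 1 are used, untruncated).
#' @param family one of "exponential", "power_law", "composite".
#' @return an object of class `decay_model_fit`: list with `family`,
#'   `coefficients`, `RSS`, `n_points`, `LL`, `K`, `AICc`, `converged`,
#'   `n_restarts`.
#' @export
fit_decay_model <- function(points, family = decay_families) {
  family <- match.arg(family)
  df <- as.data.frame(points)
  if (!all(c("d", "mi_adj") %in% names(df))) {
    stop("points must have columns d and mi_adj", call. = FALSE)
  }
  df <- df[df$d >= 1, c("d", "mi_adj")]
  if (any(!is.finite(df$mi_adj))) stop("non-finite mi_adj values", call. = FALSE)
  n_coef <- if (family == "composite") 4L else 2L
  k_par <- n_coef + 1L
  if (nrow(df) < k_par + 1L) {
    stop("fit infeasible for family '", family, "': ", nrow(df),
         " points < ", k_par + 1L, " required", call. = FALSE)
  }
  starts <- start_grid(family, df$mi_adj)
  bounds <- fit_bounds(family)
  best <- NULL
  n_used <- 0L
  for (r in seq_len(nrow(starts))) {
    st <- as.list(starts[r, , drop = FALSE])
    fit <- tryCatch(
      suppressWarnings(minpack.lm::nlsLM(
        decay_formula(family), data = df, start = st,
        lower = bounds$lower, upper = bounds$upper,
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    n_used <- n_used + 1L
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    out <- structure(
      list(family = family, coefficients = NULL, RSS = NA_real_,
           n_points = nrow(df), LL = NA_real_, K = k_par, AICc = NA_real_,
           converged = FALSE, n_restarts = n_used),
      class = "decay_model_fit")
    return(out)
  }
  co <- stats::coef(best$fit)
  out <- structure(
    list(family = family, coefficients = co, RSS = best$rss,
         n_points = nrow(df), LL = NA_real_, K = k_par, AICc = NA_real_,
         converged = TRUE, n_restarts = n_used),
    class = "decay_model_fit")
  gaussian_ll_aicc(out)
}

#' Gaussian log-likelihood and AICc of a least-squares fit
#'
#' Under iid Gaussian residuals with the error variance profiled out,
#' \eqn{LL = -(n/2)[\ln(2\pi) + \ln(RSS/n) + 1]}. The parameter count K is
#' the number of fitted coefficients plus one for the error variance (K = 3
#' for the two-coefficient families, K = 5 for the composite), and
#' \eqn{AICc = 2K - 2LL + 2K(K+1)/(n - K - 1)}.
#'
#' @param fit a converged `decay_model_fit` with `RSS` and `n_points` set.
#' @return the fit with `LL`, `K` and `AICc` filled in.
#' @export
gaussian_ll_aicc <- function(fit) {
  stopifnot(inherits(fit, "decay_model_fit"))
  if (!isTRUE(fit$converged)) return(fit)
  n <- fit$n_points
  k <- fit$K
  if (n <= k + 1L) stop("AICc undefined: n_points <= K + 1", call. = FALSE)
  # RSS below ~1e-15 is indistinguishable from an exact fit at double
  # precision; flooring it lets K decide between exactly-fitting families
  # instead of rounding noise in the log-likelihood.
  rss <- max(fit$RSS, 1e-15)
  fit$LL <- -(n / 2) * (log(2 * pi) + log(rss / n) + 1)
  fit$AICc <- 2 * k - 2 * fit$LL + 2 * k * (k + 1) / (n - k - 1)
  fit
}

#' @export
print.decay_model_fit <- function(x, ...) {
  cat("<decay_model_fit>", x$family,
      if (x$converged) "" else "(NOT CONVERGED)", "\n")
  if (x$converged) {
    cat("  coefficients:",
        paste(names(x$coefficients),
              format(x$coefficients, digits = 4), sep = "=", collapse = ", "),
        "\n  RSS =", format(x$RSS, digits = 4),
        ", n =", x$n_points, ", K =", x$K,
        ", AICc =", format(x$AICc, digits = 5), "\n")
  }
  invisible(x)
}

#' Akaike weights from AICc differences
#'
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}.
#'
#' @param delta numeric vector of AICc differences (min must be 0 or is
#'   subtracted).
#' @return numeric vector of weights summing to 1.
#' @export
akaike_weights <- function(delta) {
  delta <- delta - min(delta)
  w <- exp(-delta / 2)
  w / sum(w)
}

#' Compare fitted decay models by AICc
#'
#' Ranks converged fits by AICc, computes AICc differences, Akaike weights
#' and cumulative weights. A family is the sole best model iff it is the only
#' one with an AICc difference below `tie_threshold`; otherwise all families
#' under the threshold form a competing best set.
#'
#' @param fits list of `decay_model_fit` objects (non-converged fits are
#'   dropped with a record).
#' @param tie_threshold AICc difference below which models are considered
#'   competing (default 2.0).
#' @return an object of class `model_comparison`: list with `table` (data
#'   frame: family, K, AICc, dAICc, weight, cum_weight, LL, ordered by
#'   preference), `best_set`, `sole_best` (family name or NA),
#'   `n_failed`.
#' @export
compare_models <- function(fits, tie_threshold = 2.0) {
  ok <- Filter(function(f) isTRUE(f$converged) && is.finite(f$AICc), fits)
  if (length(ok) == 0L) stop("no converged fits to compare", call. = FALSE)
  tab <- data.frame(
    family = vapply(ok, `[[`, character(1), "family"),
    K = vapply(ok, `[[`, integer(1), "K"),
    AICc = vapply(ok, `[[`, numeric(1), "AICc"),
    LL = vapply(ok, `[[`, numeric(1), "LL"),
    stringsAsFactors = FALSE
  )
  tab$dAICc <- tab$AICc - min(tab$AICc)
  tab$weight <- akaike_weights(tab$dAICc)
  tab <- tab[order(tab$AICc), , drop = FALSE]
  tab$cum_weight <- cumsum(tab$weight)
  tab <- tab[, c("family", "K", "AICc", "dAICc", "weight", "cum_weight", "LL")]
  rownames(tab) <- NULL
  best_set <- tab$family[tab$dAICc < tie_threshold]
  structure(
    list(table = tab,
         best_set = best_set,
         sole_best = if (length(best_set) == 1L) best_set else NA_character_,
         n_failed = length(fits) - length(ok)),
    class = "model_comparison"
  )
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>\n")
  print(transform(x$table, AICc = round(AICc, 1), dAICc = round(dAICc, 1),
                  weight = round(weight, 2), cum_weight = round(cum_weight, 2),
                  LL = round(LL, 1)))
  if (!is.na(x$sole_best)) cat("sole best:", x$sole_best, "\n")
  else cat("competing models:", paste(x$best_set, collapse = ", "), "\n")
  invisible(x)
}

#' Fit and compare all three decay families on a truncated curve
#'
#' Convenience wrapper: truncates the curve at its maximum dependency
#' distance (distances 1..D; optionally 1..D-1 via `drop_last_point`, a
#' convention some published selection tables follow), fits the exponential,
#' power-law and composite families, and compares them.
#'
#' @param curve an `mi_decay_curve`.
#' @param tie_threshold see [compare_models()].
#' @param drop_last_point fit on distances 1..D-1 instead of 1..D.
#' @return list with `max_distance` (list distance/censored), `fits`,
#'   `comparison` (NULL when fewer than one family is feasible/converged).
#' @export
select_decay_model <- function(curve, tie_threshold = 2.0,
                               drop_last_point = FALSE) {
  mdd <- max_dependency_distance(curve)
  d_hi <- if (drop_last_point) mdd$distance - 1L else mdd$distance
  pts <- as.data.frame(curve)
  pts <- pts[pts$d >= 1L & pts$d <= d_hi, c("d", "mi_adj")]
  fits <- lapply(decay_families, function(fam) {
    tryCatch(fit_decay_model(pts, fam), error = function(e) {
      structure(list(family = fam, coefficients = NULL, RSS = NA_real_,
                     n_points = nrow(pts), LL = NA_real_,
                     K = if (fam == "composite") 5L else 3L, AICc = NA_real_,
                     converged = FALSE, n_restarts = 0L,
                     error = conditionMessage(e)),
                class = "decay_model_fit")
    })
  })
  names(fits) <- decay_families
  comparison <- tryCatch(compare_models(fits, tie_threshold),
                         error = function(e) NULL)
  list(max_distance = mdd, fits = fits, comparison = comparison)
}
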