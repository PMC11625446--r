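#' Estimate an MI decay curve with a permutation chance floor
#'
#' For each inter-element distance d in 0..`d_max`, estimates
#' \eqn{\widehat{MI}(d)} from the observed stream, then builds a chance
#' floor: the stream is uniformly shuffled once per permutation replicate,
#' and \eqn{\widehat{MI}_{sh}(d)} combines the observed marginal entropies
#' with the joint entropy of the shuffled stream at distance d. The adjusted
#' score is \eqn{MI_{Adj}(d) = \widehat{MI}(d) - \mathrm{mean}\,
#' \widehat{MI}_{sh}(d)}, and the significance margin is
#' \eqn{\widehat{MI}(d)} minus the upper 95% percentile of the permutation
#' distribution. Marginal entropies are always taken from the paired
#' positions of the observed stream (first and last N - d symbols), keeping
#' the MI identity internally consistent at every distance.
#'
#' @param stream a `token_stream`.
#' @param d_max maximum distance (default 100). Truncated with a warning if
#'   it reaches the stream length.
#' @param n_perm number of permutation replicates (default 1000; >= 2).
#' @param seed integer seed making the permutations reproducible.
#' @param correction apply the Grassberger correction (default TRUE).
#' @param exclude_cross_boundary drop pairs spanning two source sequences
#'   (requires boundary labels on the stream).
#' @param ci percentile confidence level for the chance floor (default 0.95).
#' @return an object of class `mi_decay_curve`: a data frame with one row per
#'   distance and columns `d`, `mi_hat`, `mi_sh_mean`, `mi_sh_lo`,
#'   `mi_sh_hi`, `mi_adj`, `margin`; attributes `N`, `n_perm`, `seed`,
#'   `d_max`, `correction`.
#' @seealso [max_dependency_distance()] for the dependency-range rule,
#'   [fit_decay_model()] for decay-model fitting.
#' @export
estimate_decay_curve <- function(stream, d_max = 100L, n_perm = 1000L,
                                 seed = NULL, correction = TRUE,
                                 exclude_cross_boundary = FALSE, ci = 0.95) {
  stopifnot(inherits(stream, "token_stream"))
  n <- stream$N
  if (n < 2L) stop("stream must contain at least 2 symbols", call. = FALSE)
  if (n_perm < 2L) stop("n_perm must be >= 2", call. = FALSE)
  if (d_max >= n) {
    warning("d_max >= stream length; curve truncated to d_max = ", n - 1L)
    d_max <- n - 1L
  }
  d_max <- as.integer(d_max)
  if (!is.null(seed)) set.seed(seed)
  k <- length(stream$alphabet)
  codes <- stream$codes
  dg <- digamma(seq_len(n))
  dists <- 0:d_max

  keep_idx <- vector("list", d_max + 1L)
  use_mask <- exclude_cross_boundary && !is.null(stream$boundaries)

  mi_hat <- numeric(d_max + 1L)
  sx <- numeric(d_max + 1L)
  sy <- numeric(d_max + 1L)
  for (d in dists) {
    i <- seq_len(n - d)
    if (use_mask) {
      keep <- stream$boundaries[i] == stream$boundaries[i + d]
      i <- i[keep]
      if (length(i) == 0L) stop("no within-sequence pairs at distance ", d,
                                call. = FALSE)
      keep_idx[[d + 1L]] <- i
    }
    x <- codes[i]; y <- codes[i + d]
    cx <- tabulate(x, nbins = k); cy <- tabulate(y, nbins = k)
    cj <- tabulate((x - 1L) * k + y, nbins = k * k)
    sx[d + 1L] <- .entropy_bits(cx[cx > 0], dg, correction)
    sy[d + 1L] <- .entropy_bits(cy[cy > 0], dg, correction)
    mi_hat[d + 1L] <- sx[d + 1L] + sy[d + 1L] -
      .entropy_bits(cj[cj > 0], dg, correction)
  }

  mi_sh <- matrix(NA_real_, nrow = n_perm, ncol = d_max + 1L)
  for (p in seq_len(n_perm)) {
    sh <- codes[sample.int(n)]
    for (d in dists) {
      i <- if (use_mask) keep_idx[[d + 1L]] else seq_len(n - d)
      cj <- tabulate((sh[i] - 1L) * k + sh[i + d], nbins = k * k)
      mi_sh[p, d + 1L] <- sx[d + 1L] + sy[d + 1L] -
        .entropy_bits(cj[cj > 0], dg, correction)
    }
  }

  alpha <- (1 - ci) / 2
  qs <- apply(mi_sh, 2L, stats::quantile, probs = c(alpha, 1 - alpha),
              names = FALSE)
  out <- data.frame(
    d = dists,
    mi_hat = mi_hat,
    mi_sh_mean = colMeans(mi_sh),
    mi_sh_lo = qs[1L, ],
    mi_sh_hi = qs[2L, ]
  )
  out$mi_adj <- out$mi_hat - out$mi_sh_mean
  out$margin <- out$mi_hat - out$mi_sh_hi
  attr(out, "N") <- n
  attr(out, "n_perm") <- as.integer(n_perm)
  attr(out, "seed") <- seed
  attr(out, "d_max") <- d_max
  attr(out, "correction") <- correction
  class(out) <- c("mi_decay_curve", "data.frame")
  out
}

#' Maximum distance at which dependencies are detected
#'
#' The curve's significance margin at distance d is
#' \eqn{\widehat{MI}(d) - CI^{upper}_{95\%}\{\widehat{MI}_{sh}(d)\}}. The
#' first distance d >= 1 at which this margin falls below zero marks where MI
#' is no longer distinguishable from chance; the dependency range is the
#' distance immediately before it. If the margin never falls below zero up to
#' `d_max`, the range is censored at `d_max`. Downstream model fitting
#' truncates the curve to distances up to this value.
#'
#' @param curve an `mi_decay_curve`.
#' @return list with `distance` (integer) and `censored` (logical).
#' @export
max_dependency_distance <- function(curve) {
  stopifnot(inherits(curve, "mi_decay_curve"))
  pos <- curve[curve$d >= 1L, ]
  below <- which(pos$margin < 0)
  if (length(below) == 0L) {
    list(distance = max(pos$d), censored = TRUE)
  } else {
    list(distance = pos$d[below[1L]] - 1L, censored = FALSE)
  }
}

#' Write an MI decay curve and its metadata to disk
#'
#' Writes the per-distance table as TSV and a JSON sidecar carrying N,
#' n_perm, seed and the censoring flag.
#'
#' @param curve an `mi_decay_curve`.
#' @param path output TSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_decay_curve <- function(curve, path) {
  stopifnot(inherits(curve, "mi_decay_curve"))
  utils::write.table(as.data.frame(curve), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  mdd <- max_dependency_distance(curve)
  meta <- list(N = attr(curve, "N"), n_perm = attr(curve, "n_perm"),
               seed = attr(curve, "seed"), d_max = attr(curve, "d_max"),
               max_dependency_distance = mdd$distance,
               censored = mdd$censored)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       null = "null")
  invisible(path)
}
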