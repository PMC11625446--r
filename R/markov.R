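#' Fit a first-order Markov chain by maximum likelihood
#'
#' Transition probabilities are bigram-frequency ratios,
#' T[i, j] = count(i -> j) / count(i -> .), over the lexicographically
#' ordered observed alphabet. States never observed as a transition source
#' (a unique stream-final symbol) receive a self-loop row, with a warning,
#' so the matrix stays row-stochastic. Irreducibility is decided by strong
#' connectivity of the positive-transition digraph and the period is the gcd
#' of its cycle lengths (1 = aperiodic); both are computed, never assumed.
#' Irreducible aperiodic chains guarantee MI decay to zero rather than to a
#' positive constant, which is what licenses fitting decay models without an
#' additive offset.
#'
#' @param stream a `token_stream` with at least 2 symbols (a single-symbol
#'   alphabet yields a degenerate one-state chain, flagged).
#' @return an object of class `markov_chain_model`: list with `states`,
#'   `transition` (row-stochastic matrix), `irreducible`, `period`,
#'   `degenerate`, `initial` (empirical first-symbol frequencies over
#'   source-sequence starts, or the stream start), `source_id`.
#' @export
fit_markov <- function(stream) {
  stopifnot(inherits(stream, "token_stream"))
  if (stream$N < 2L) stop("need at least 2 symbols to fit a chain", call. = FALSE)
  present <- sort(unique(stream$codes))
  states <- stream$alphabet[present]
  k <- length(states)
  idx <- match(stream$codes, present)
  from <- idx[-stream$N]
  to <- idx[-1L]
  counts <- matrix(tabulate((from - 1L) * k + to, nbins = k * k),
                   nrow = k, ncol = k, byrow = TRUE,
                   dimnames = list(states, states))
  out_deg <- rowSums(counts)
  trans <- counts / ifelse(out_deg > 0, out_deg, 1)
  if (any(out_deg == 0)) {
    warning("state(s) with no observed outgoing transition given a self-loop: ",
            paste(states[out_deg == 0], collapse = ", "))
    for (i in which(out_deg == 0)) trans[i, i] <- 1
  }
  g <- igraph::graph_from_adjacency_matrix(trans > 0, mode = "directed")
  irreducible <- igraph::is_connected(g, mode = "strong")
  period <- if (k == 1L) 1L else chain_period(trans > 0)
  first <- tabulate(idx[1L], nbins = k)
  if (!is.null(stream$boundaries)) {
    starts <- idx[!duplicated(stream$boundaries)]
    first <- tabulate(starts, nbins = k)
  }
  structure(
    list(states = states, transition = trans,
         irreducible = irreducible, period = period,
         degenerate = k == 1L,
         initial = stats::setNames(first / sum(first), states),
         source_id = NULL),
    class = "markov_chain_model"
  )
}

# Period of the positive-transition digraph: BFS level labelling from the
# first state of each strongly connected component; the gcd of
# (level[u] + 1 - level[v]) over within-component edges u -> v gives the
# cycle-length gcd. Returns the gcd across all non-trivial components
# (the standard chain period when the chain is irreducible).
chain_period <- function(adj) {
  k <- nrow(adj)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(g, mode = "strong")$membership
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  per <- 0L
  for (cc in unique(comp)) {
    nodes <- which(comp == cc)
    has_edge <- any(adj[nodes, nodes, drop = FALSE])
    if (!has_edge) next
    level <- rep(NA_integer_, k)
    level[nodes[1L]] <- 0L
    queue <- nodes[1L]
    while (length(queue)) {
      u <- queue[1L]; queue <- queue[-1L]
      for (v in nodes[adj[u, nodes]]) {
        if (is.na(level[v])) {
          level[v] <- level[u] + 1L
          queue <- c(queue, v)
        }
        per <- gcd2(per, abs(level[u] + 1L - level[v]))
      }
    }
  }
  if (per == 0L) NA_integer_ else as.integer(per)
}

#' Stationary distribution of a Markov chain
#'
#' Solves pi = pi T by the left eigenvector of the transition matrix.
#'
#' @param model a `markov_chain_model` (must be irreducible).
#' @return named numeric vector summing to 1.
#' @export
stationary_distribution <- function(model) {
  stopifnot(inherits(model, "markov_chain_model"))
  if (!model$irreducible) stop("chain is reducible; no unique stationary distribution",
                               call. = FALSE)
  e <- eigen(t(model$transition))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  stats::setNames(v / sum(v), model$states)
}

#' Simulate a token stream from a fitted Markov chain
#'
#' The initial state is drawn from the chain's stationary distribution; for
#' reducible chains the empirical start-symbol frequencies are used instead,
#' with a warning. `init = "empirical"` forces the empirical start
#' distribution.
#'
#' @param model a `markov_chain_model`.
#' @param length stream length (>= 1).
#' @param seed integer seed.
#' @param init "stationary" (default) or "empirical".
#' @return a `token_stream` over the chain's states.
#' @export
simulate_stream <- function(model, length, seed = NULL,
                            init = c("stationary", "empirical")) {
  stopifnot(inherits(model, "markov_chain_model"), length >= 1)
  init <- match.arg(init)
  if (!is.null(seed)) set.seed(seed)
  k <- length(model$states)
  p0 <- if (init == "stationary" && model$irreducible) {
    stationary_distribution(model)
  } else {
    if (init == "stationary" && !model$irreducible) {
      warning("reducible chain: falling back to empirical start frequencies")
    }
    model$initial
  }
  cum <- t(apply(model$transition, 1L, cumsum))
  out <- integer(length)
  out[1L] <- sample.int(k, 1L, prob = p0)
  if (length > 1L) {
    u <- stats::runif(length - 1L)
    for (i in 2:length) {
      out[i] <- findInterval(u[i - 1L], cum[out[i - 1L], ]) + 1L
    }
  }
  token_stream(model$states[out], alphabet = model$states)
}

#' Garwood exact Poisson confidence interval for a mean of counts
#'
#' Treats the sum of `n` observed counts as Poisson and applies the Garwood
#' chi-square construction, then rescales to the mean:
#' lower = qchisq(alpha/2, 2S) / (2n), upper = qchisq(1 - alpha/2,
#' 2(S + 1)) / (2n).
#'
#' @param counts non-negative counts (e.g. per-simulation maximum distances).
#' @param conf confidence level (default 0.95).
#' @return list with `mean`, `lower`, `upper`, `total`, `n`.
#' @export
poisson_exact_ci <- function(counts, conf = 0.95) {
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  n <- length(counts)
  s <- sum(counts)
  alpha <- 1 - conf
  lower <- if (s == 0) 0 else stats::qchisq(alpha / 2, 2 * s) / 2
  upper <- stats::qchisq(1 - alpha / 2, 2 * (s + 1)) / 2
  list(mean = s / n, lower = lower / n, upper = upper / n, total = s, n = n)
}

#' Null distribution of the maximum dependency distance under a Markov chain
#'
#' Simulates `n_sims` streams of the observed corpus length from the fitted
#' chain, runs the full MI decay estimation on each (same distance range,
#' permutation count and CI rule as the observed analysis), and collects the
#' maximum dependency distance of each simulation. The mean of the maxima
#' gets a Garwood exact Poisson CI; the observed maximum is judged `greater`
#' iff it exceeds the CI's upper limit.
#'
#' @param model a `markov_chain_model`.
#' @param corpus_length length of the observed corpus being tested.
#' @param observed_max observed maximum dependency distance (integer).
#' @param n_sims number of null sequences (default 100).
#' @param d_max,n_perm,ci MI estimation parameters, matching the observed
#'   analysis.
#' @param seed integer seed driving all simulations and permutations.
#' @return an object of class `null_max_distance`: list with `maxima`,
#'   `mean`, `ci_lower`, `ci_upper`, `observed`, `verdict` ("greater" or
#'   "not_greater"), `n_failed`, `censored` (count of censored simulation
#'   maxima).
#' @export
null_max_distance <- function(model, corpus_length, observed_max,
                              n_sims = 100L, d_max = 100L, n_perm = 1000L,
                              ci = 0.95, seed = NULL) {
  stopifnot(inherits(model, "markov_chain_model"))
  if (!is.null(seed)) set.seed(seed)
  maxima <- rep(NA_real_, n_sims)
  censored <- 0L
  for (s in seq_len(n_sims)) {
    res <- tryCatch({
      sim <- simulate_stream(model, corpus_length)
      curve <- estimate_decay_curve(sim, d_max = min(d_max, corpus_length - 1L),
                                    n_perm = n_perm, ci = ci)
      max_dependency_distance(curve)
    }, error = function(e) NULL)
    if (is.null(res)) next
    maxima[s] <- res$distance
    if (res$censored) censored <- censored + 1L
  }
  ok <- maxima[!is.na(maxima)]
  if (length(ok) == 0L) stop("all null simulations failed", call. = FALSE)
  ci_out <- poisson_exact_ci(ok, conf = ci)
  structure(
    list(maxima = ok, mean = ci_out$mean, ci_lower = ci_out$lower,
         ci_upper = ci_out$upper, observed = observed_max,
         verdict = if (observed_max > ci_out$upper) "greater" else "not_greater",
         n_failed = n_sims - length(ok), censored = censored),
    class = "null_max_distance"
  )
}

#' @export
print.null_max_distance <- function(x, ...) {
  cat("<null_max_distance> observed =", x$observed,
      "; null mean =", format(x$mean, digits = 3),
      sprintf("[%.2f, %.2f]", x$ci_lower, x$ci_upper),
      "->", x$verdict, "\n")
  invisible(x)
}

#' Pool corpora into a community stream
#'
#' Concatenates the streams of all individuals end-to-end in alphabetical
#' order of individual id; with `condensed = TRUE` each individual's stream
#' is condensed before pooling.
#'
#' @param corpora named list of `action_corpus` objects.
#' @param condensed condense each stream first (default FALSE).
#' @return a `token_stream` over the union alphabet.
#' @export
pool_corpora <- function(corpora, condensed = FALSE) {
  corpora <- corpora[order(names(corpora))]
  streams <- lapply(corpora, function(cp) {
    s <- cp$stream
    if (condensed) s <- condense(s) else s
  })
  syms <- unlist(lapply(streams, stream_symbols), use.names = FALSE)
  token_stream(syms)
}

#' Community Markov false-positive experiment
#'
#' Fits a community Markov chain to the pooled stream, simulates
#' `n_sequences` independent sequences of `sim_length` elements, and runs
#' the full analysis on each: MI decay curve, truncation at the maximum
#' dependency distance, three-family fit and AICc comparison. The summary
#' tallies how often each family is the sole best model, how often the
#' comparison is tied, and how many sequences allowed all three families to
#' be fitted; since a first-order chain has no hierarchical structure,
#' non-exponential winners here measure the false-positive rate of
#' power-law detection.
#'
#' @param pooled a pooled `token_stream` (see [pool_corpora()]).
#' @param n_sequences number of simulated sequences (default 500).
#' @param sim_length length of each sequence (default 1000).
#' @param d_max,n_perm MI estimation parameters (defaults 100 and 1000).
#' @param tie_threshold AICc tie threshold (default 2.0).
#' @param seed integer seed.
#' @return an object of class `community_summary`: list with `model` (the
#'   community chain), `per_sequence` (data frame: sequence, max_distance,
#'   censored, all_fitted, sole_best, n_best), `n_sequences`,
#'   `n_all_fitted`, `counts` (sole-best per family plus ties over fitted
#'   comparisons), `proportions`.
#' @export
community_experiment <- function(pooled, n_sequences = 500L,
                                 sim_length = 1000L, d_max = 100L,
                                 n_perm = 1000L, tie_threshold = 2.0,
                                 seed = NULL) {
  stopifnot(inherits(pooled, "token_stream"))
  if (!is.null(seed)) set.seed(seed)
  model <- fit_markov(pooled)
  rows <- vector("list", n_sequences)
  for (s in seq_len(n_sequences)) {
    row <- data.frame(sequence = s, max_distance = NA_integer_,
                      censored = NA, all_fitted = FALSE,
                      sole_best = NA_character_, n_best = NA_integer_,
                      stringsAsFactors = FALSE)
    res <- tryCatch({
      sim <- simulate_stream(model, sim_length)
      curve <- estimate_decay_curve(sim, d_max = d_max, n_perm = n_perm)
      select_decay_model(curve, tie_threshold)
    }, error = function(e) NULL)
    if (!is.null(res)) {
      row$max_distance <- res$max_distance$distance
      row$censored <- res$max_distance$censored
      n_conv <- sum(vapply(res$fits, function(f) isTRUE(f$converged), logical(1)))
      row$all_fitted <- n_conv == 3L
      if (!is.null(res$comparison) && row$all_fitted) {
        row$sole_best <- res$comparison$sole_best
        row$n_best <- length(res$comparison$best_set)
      }
    }
    rows[[s]] <- row
  }
  per_seq <- do.call(rbind, rows)
  fitted <- per_seq[per_seq$all_fitted, , drop = FALSE]
  counts <- c(
    exponential = sum(fitted$sole_best == "exponential", na.rm = TRUE),
    power_law = sum(fitted$sole_best == "power_law", na.rm = TRUE),
    composite = sum(fitted$sole_best == "composite", na.rm = TRUE),
    tie = sum(fitted$n_best > 1L, na.rm = TRUE)
  )
  n_fit <- nrow(fitted)
  structure(
    list(model = model, per_sequence = per_seq,
         n_sequences = n_sequences, n_all_fitted = n_fit,
         counts = counts,
         proportions = if (n_fit > 0) counts / n_fit else counts * NA_real_),
    class = "community_summary"
  )
}

#' @export
print.community_summary <- function(x, ...) {
  cat("<community_summary>", x$n_all_fitted, "of", x$n_sequences,
      "sequences with all three models fitted\n")
  print(round(x$proportions, 3))
  invisible(x)
}
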