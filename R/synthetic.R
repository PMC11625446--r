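#' Random row-stochastic transition matrix
#'
#' Rows are independent Dirichlet(alpha) draws; small alpha concentrates
#' probability on few targets, giving strongly structured (but almost surely
#' irreducible and aperiodic) chains.
#'
#' @param n_states number of states.
#' @param alpha Dirichlet concentration (default 0.3).
#' @param states optional state names (default "s01", "s02", ...).
#' @return row-stochastic matrix.
#' @export
random_transition_matrix <- function(n_states, alpha = 0.3, states = NULL) {
  if (is.null(states)) states <- sprintf("s%02d", seq_len(n_states))
  g <- matrix(stats::rgamma(n_states * n_states, shape = alpha),
              nrow = n_states, dimnames = list(states, states))
  g / rowSums(g)
}

check_simplex_rows <- function(m) {
  if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-8)) {
    stop("transition matrix rows must be probability simplexes", call. = FALSE)
  }
}

as_chain <- function(states, transition) {
  g <- igraph::graph_from_adjacency_matrix(transition > 0, mode = "directed")
  structure(
    list(states = states, transition = transition,
         irreducible = igraph::is_connected(g, mode = "strong"),
         period = chain_period(transition > 0),
         degenerate = length(states) == 1L,
         initial = stats::setNames(rep(1 / length(states), length(states)),
                                   states),
         source_id = NULL),
    class = "markov_chain_model"
  )
}

#' Generate a Markovian token stream
#'
#' Embodies the purely Markovian structural hypothesis: all sequential
#' structure comes from adjacent transition probabilities, so MI decays
#' exponentially. With `transition = NULL` a random ergodic chain over
#' `n_states` states is drawn first as a sticky Dirichlet chain,
#' T = stickiness * I + (1 - stickiness) * D with Dirichlet(alpha) rows D.
#' The self-transition mass mirrors the action repetition that dominates
#' real tool-use corpora and gives the chain a dominant relaxation mode, so
#' its MI decay is close to a single exponential with a dependency range of
#' a few elements.
#'
#' @param length stream length (default 2000).
#' @param transition optional row-stochastic matrix with named rows.
#' @param n_states,alpha,stickiness used when `transition` is NULL (defaults
#'   10, 0.5, 0.35).
#' @param seed integer seed (drives both the chain draw and the simulation).
#' @return a `token_stream` with attributes `ground_truth = "markov"` and
#'   `chain` (the generating `markov_chain_model`).
#' @export
gen_markov <- function(length = 2000L, transition = NULL, n_states = 10L,
                       alpha = 0.5, stickiness = 0.35, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.null(transition)) {
    d <- random_transition_matrix(n_states, alpha)
    transition <- stickiness * diag(n_states) + (1 - stickiness) * d
    dimnames(transition) <- dimnames(d)
  }
  check_simplex_rows(transition)
  states <- rownames(transition)
  if (is.null(states)) states <- sprintf("s%02d", seq_len(nrow(transition)))
  chain <- as_chain(states, transition)
  out <- simulate_stream(chain, length)
  attr(out, "ground_truth") <- "markov"
  attr(out, "chain") <- chain
  out
}

expand_once <- function(symbols, k, alphabet, mutation, rules) {
  if (!is.null(rules)) {
    return(unlist(rules[symbols], use.names = FALSE))
  }
  n <- length(symbols)
  children <- rep(symbols, each = k)
  mutate <- stats::runif(n * k) < mutation
  children[mutate] <- alphabet[sample.int(length(alphabet), sum(mutate),
                                          replace = TRUE)]
  children
}

#' Generate a hierarchical token stream
#'
#' Embodies the purely hierarchical structural hypothesis via a deep
#' branching (substitution) process: starting from a root symbol, every
#' symbol expands into `k` children for `depth` generations and the leaves,
#' read left to right, form the stream (length k^depth). In the stochastic
#' mode each child copies its parent with probability 1 - `mutation` and is
#' otherwise drawn uniformly from the alphabet; such deep generative trees
#' produce statistical dependencies whose MI decays as a power law.
#' Deterministic substitution systems (e.g. A -> AB, B -> BA) are available
#' via `rules`.
#'
#' @param depth number of expansion generations (>= 2 for long-range
#'   structure; depth 1 is a single substitution).
#' @param k branching factor (default 2).
#' @param alphabet_size alphabet size for the stochastic mode (default 8).
#' @param mutation per-child mutation probability (default 0.25).
#' @param rules optional named list mapping each symbol to its character
#'   vector of k children (deterministic mode).
#' @param root root symbol (default first alphabet symbol).
#' @param length optional truncation length (<= k^depth).
#' @param length_cap guard against runaway expansion (default 2^21).
#' @param seed integer seed.
#' @return a `token_stream` with `ground_truth = "hierarchical"`.
#' @export
gen_hierarchical <- function(depth, k = 2L, alphabet_size = 8L,
                             mutation = 0.25, rules = NULL, root = NULL,
                             length = NULL, length_cap = 2^21, seed = NULL) {
  if (k < 2L && is.null(rules)) stop("branching factor k must be >= 2", call. = FALSE)
  if (k^depth > length_cap) stop("k^depth exceeds the length cap", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  alphabet <- if (!is.null(rules)) sort(names(rules)) else
    sprintf("h%02d", seq_len(alphabet_size))
  if (is.null(root)) root <- alphabet[1L]
  symbols <- root
  for (i in seq_len(depth)) {
    symbols <- expand_once(symbols, k, alphabet, mutation, rules)
  }
  if (!is.null(length)) {
    if (length > base::length(symbols)) stop("requested length exceeds k^depth",
                                             call. = FALSE)
    symbols <- symbols[seq_len(length)]
  }
  out <- token_stream(symbols, alphabet = alphabet)
  attr(out, "ground_truth") <- "hierarchical"
  out
}

# Near-deterministic internal chain over a subroutine's private symbols:
# with probability 1 - noise follow a fixed cycle, otherwise jump uniformly.
subroutine_chain <- function(symbols, noise = 0.1) {
  k <- length(symbols)
  trans <- matrix(noise / k, nrow = k, ncol = k,
                  dimnames = list(symbols, symbols))
  nxt <- c(seq_len(k)[-1L], 1L)
  for (i in seq_len(k)) trans[i, nxt[i]] <- trans[i, nxt[i]] + (1 - noise)
  trans
}

#' Generate a composite token stream with known subroutine boundaries
#'
#' Embodies the composite structural hypothesis: short subroutines, each an
#' internal first-order Markov chain over its own private symbols, are
#' arranged into a long sequence by the same hierarchical branching process
#' used by [gen_hierarchical()] (applied to subroutine identities). Each
#' emitted subroutine has a length drawn uniformly from
#' [`L_min`, `L_max`]; the emitted boundaries are recorded so recovery tests
#' can score transition-point estimates against the true subroutine length.
#'
#' @param n_subroutines size of the subroutine library (default 4).
#' @param L_min,L_max subroutine length range (defaults 5, 5).
#' @param depth,k,mutation hierarchical arrangement parameters (defaults 9,
#'   2, 0.25).
#' @param symbols_per_subroutine private alphabet size per subroutine
#'   (default 4).
#' @param chain_noise internal-chain noise (default 0.1).
#' @param length optional truncation length.
#' @param seed integer seed.
#' @return an object of class `composite_stream`: list with `stream` (a
#'   `token_stream`, `ground_truth = "composite"`), `subroutine_ids`
#'   (emitted order), `boundaries` (start index of each emitted subroutine),
#'   `lengths` (emitted subroutine lengths), `L_range`.
#' @export
gen_composite <- function(n_subroutines = 4L, L_min = 5L, L_max = 5L,
                          depth = 9L, k = 2L, mutation = 0.25,
                          symbols_per_subroutine = 4L, chain_noise = 0.1,
                          length = NULL, seed = NULL) {
  if (n_subroutines < 1L) stop("subroutine library must be non-empty", call. = FALSE)
  if (L_min < 1L || L_max < L_min) stop("invalid subroutine length range",
                                        call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  ids <- sprintf("r%02d", seq_len(n_subroutines))
  # arrange subroutine identities hierarchically
  arr <- gen_hierarchical(depth = depth, k = k,
                          alphabet_size = n_subroutines, mutation = mutation)
  id_seq <- ids[arr$codes]
  if (n_subroutines == 1L) warning("single subroutine: stream is periodic")
  chains <- lapply(seq_len(n_subroutines), function(s) {
    subroutine_chain(paste0(ids[s], ".",
                            letters[seq_len(symbols_per_subroutine)]),
                     noise = chain_noise)
  })
  names(chains) <- ids
  pieces <- vector("list", base::length(id_seq))
  lens <- integer(base::length(id_seq))
  for (j in seq_along(id_seq)) {
    trans <- chains[[id_seq[j]]]
    L <- if (L_min == L_max) L_min else
      sample(seq.int(L_min, L_max), 1L)
    syms <- character(L)
    cur <- sample.int(nrow(trans), 1L)
    syms[1L] <- rownames(trans)[cur]
    if (L > 1L) for (t in 2:L) {
      cur <- sample.int(nrow(trans), 1L, prob = trans[cur, ])
      syms[t] <- rownames(trans)[cur]
    }
    pieces[[j]] <- syms
    lens[j] <- L
  }
  symbols <- unlist(pieces, use.names = FALSE)
  boundaries <- cumsum(c(1L, lens[-base::length(lens)]))
  if (!is.null(length) && length < base::length(symbols)) {
    symbols <- symbols[seq_len(length)]
    keep <- boundaries <= length
    boundaries <- boundaries[keep]
    id_seq <- id_seq[keep]
    lens <- lens[keep]
  }
  stream <- token_stream(symbols)
  attr(stream, "ground_truth") <- "composite"
  structure(
    list(stream = stream, subroutine_ids = id_seq, boundaries = boundaries,
         lengths = lens, L_range = c(L_min, L_max)),
    class = "composite_stream"
  )
}

# manipulation verbs and objects for the toy ethogram
.nut_manips <- c("strikeonehand", "eat", "grasp", "place", "peel", "pass",
                 "reorient", "bite", "kiss", "hold", "pound", "pick", "drop",
                 "rotate", "push", "pull", "tap", "lift", "crack", "sweep",
                 "touch", "turn", "collect", "inspect", "shift", "press",
                 "slide", "carry", "split", "wipe", "stack", "throw", "roll",
                 "scrape")
.nut_objects <- c("NUT", "HAMMER", "ANVIL", "KERNEL", "SHELL", "HAND")

nutcracking_alphabet <- function(alphabet_size) {
  top5 <- c("strikeonehand HAMMER", "eat KERNEL", "grasp NUT", "place NUT",
            "grasp KERNEL")
  pool <- as.vector(outer(.nut_manips, .nut_objects, paste))
  pool <- setdiff(pool, top5)
  if (alphabet_size < 6L) stop("alphabet_size must be at least 6", call. = FALSE)
  c(top5, pool[seq_len(alphabet_size - 5L)])
}

#' Generate a toy nut-cracking corpus
#'
#' Emulates the statistical shape of a wild nut-cracking action corpus: a
#' heavily skewed token-frequency profile in which the five most frequent
#' actions (strike, eat kernel, grasp nut, place nut, grasp kernel) jointly
#' carry a configurable share of the corpus (default 63%), runs of repeated
#' actions (e.g. successive hammer strikes), fragmentation into sequences,
#' and per-nut episode annotations with a configurable mean episode length.
#' The long tail is Zipf-distributed over the remaining alphabet. It does
#' NOT emulate latent subroutine structure; use [gen_composite()] for that.
#'
#' @param n_individuals number of individuals (default 8).
#' @param n_tokens tokens per individual, recycled (default 1200).
#' @param n_sequences sequences per individual, recycled (default 15).
#' @param alphabet_size number of distinct action types (default 40).
#' @param top5_share target joint share of the five head tokens (default
#'   0.63).
#' @param repeat_intensity probability that a token repeats its predecessor
#'   (default 0.25); at 0 the output contains no adjacent repeats at all, so
#'   condensing is the identity.
#' @param mean_nut_length target mean actions per nut episode (default 22).
#' @param seed integer seed.
#' @return named list of `action_corpus` objects with nut-episode
#'   annotations; attribute `audit` reports the realized top-5 share and
#'   mean per-nut length per individual against their targets.
#' @export
gen_nutcracking_corpus <- function(n_individuals = 8L, n_tokens = 1200L,
                                   n_sequences = 15L, alphabet_size = 40L,
                                   top5_share = 0.63, repeat_intensity = 0.25,
                                   mean_nut_length = 22, seed = NULL) {
  if (top5_share <= 0 || top5_share >= 1) {
    stop("infeasible top-5 share target", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  alphabet <- nutcracking_alphabet(alphabet_size)
  head_shape <- c(0.246, 0.118, 0.105, 0.086, 0.080)
  probs <- numeric(alphabet_size)
  probs[1:5] <- head_shape / sum(head_shape) * top5_share
  tail_r <- seq_len(alphabet_size - 5L)
  probs[-(1:5)] <- (1 / tail_r) / sum(1 / tail_r) * (1 - top5_share)
  n_tokens <- rep_len(n_tokens, n_individuals)
  n_sequences <- rep_len(n_sequences, n_individuals)
  inds <- sprintf("ind%02d", seq_len(n_individuals))
  all_rows <- vector("list", n_individuals)
  audit <- vector("list", n_individuals)
  for (i in seq_len(n_individuals)) {
    n <- n_tokens[i]
    toks <- alphabet[sample.int(alphabet_size, n, replace = TRUE, prob = probs)]
    if (repeat_intensity > 0) {
      rep_mask <- stats::runif(n) < repeat_intensity
      rep_mask[1L] <- FALSE
      for (t in which(rep_mask)) toks[t] <- toks[t - 1L]
    } else {
      for (t in seq_len(n)[-1L]) {
        while (toks[t] == toks[t - 1L]) {
          toks[t] <- alphabet[sample.int(alphabet_size, 1L, prob = probs)]
        }
      }
    }
    # fragment into sequences: multinomial split, at least 1 token each
    cuts <- sort(sample.int(n - 1L, n_sequences[i] - 1L))
    seq_of <- findInterval(seq_len(n) - 1L, cuts) + 1L
    # nut episodes: contiguous segments with ~Poisson(mean) lengths
    ep <- integer(n)
    pos <- 1L; ep_id <- 0L
    while (pos <= n) {
      ep_id <- ep_id + 1L
      L <- max(2L, stats::rpois(1L, mean_nut_length))
      ep[pos:min(n, pos + L - 1L)] <- ep_id
      pos <- pos + L
    }
    parts <- strsplit(toks, " ", fixed = TRUE)
    rows <- data.frame(
      individual = inds[i],
      sequence_id = sprintf("%s_seq%03d", inds[i], seq_of),
      collection_index = seq_of,
      order = stats::ave(seq_len(n), seq_of, FUN = seq_along),
      manipulation = vapply(parts, `[`, character(1), 1L),
      object = vapply(parts, `[`, character(1), 2L),
      nut_episode = sprintf("nut%04d", ep),
      stringsAsFactors = FALSE
    )
    all_rows[[i]] <- rows
    realized_top5 <- mean(toks %in% alphabet[1:5])
    audit[[i]] <- data.frame(
      individual = inds[i], target_top5 = top5_share,
      realized_top5 = realized_top5,
      target_nut_length = mean_nut_length,
      realized_nut_length = mean(table(ep)),
      stringsAsFactors = FALSE
    )
  }
  out <- corpus_from_rows(do.call(rbind, all_rows))
  attr(out, "audit") <- do.call(rbind, audit)
  out
}
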