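# Independent numerical oracles used by the property tests. These stay
# deliberately separate from the package's own code paths.

# Digamma via the recurrence psi(x) = psi(x + 1) - 1/x and the asymptotic
# series for large arguments (accurate to ~1e-12 for x >= 1).
oracle_digamma <- function(x) {
  vapply(x, function(z) {
    acc <- 0
    while (z < 20) {
      acc <- acc - 1 / z
      z <- z + 1
    }
    inv2 <- 1 / z^2
    acc + log(z) - 1 / (2 * z) -
      inv2 * (1 / 12 - inv2 * (1 / 120 - inv2 * (1 / 252 - inv2 / 240)))
  }, numeric(1))
}

# Grassberger entropy in bits from a count vector, via the oracle digamma.
oracle_grassberger <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  (log(n) - sum(counts * oracle_digamma(counts)) / n) / log(2)
}

# Analytic MI (bits) between chain states d steps apart, by matrix power.
oracle_markov_mi <- function(trans, d) {
  e <- eigen(t(trans))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi0 <- v / sum(v)
  td <- diag(nrow(trans))
  for (i in seq_len(d)) td <- td %*% trans
  joint <- diag(pi0) %*% td
  px <- rowSums(joint); py <- colSums(joint)
  h <- function(p) { p <- p[p > 0]; -sum(p * log2(p)) }
  h(px) + h(py) - h(as.vector(joint))
}

# Brute-force reachability: can i reach j in the positive-transition graph?
oracle_reachable <- function(adj) {
  k <- nrow(adj)
  r <- adj | diag(k)
  for (i in seq_len(k)) r <- r | (r %*% r > 0)
  r
}

oracle_irreducible <- function(adj) {
  r <- oracle_reachable(adj)
  all(r & t(r))
}

# gcd of return times of a reference state within each strongly connected
# component with at least one edge; matches the chain-period definition.
oracle_period <- function(adj) {
  k <- nrow(adj)
  r <- oracle_reachable(adj)
  mutual <- r & t(r)
  seen <- rep(FALSE, k)
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  per <- 0
  for (i in seq_len(k)) {
    if (seen[i]) next
    comp <- which(mutual[i, ])
    seen[comp] <- TRUE
    sub <- adj[comp, comp, drop = FALSE]
    if (!any(sub)) next
    p <- diag(length(comp))
    for (n in seq_len(4 * k)) {
      p <- (p %*% sub) > 0
      if (p[1, 1]) per <- gcd2(per, n)
    }
  }
  if (per == 0) NA_integer_ else as.integer(per)
}

# Small helper: a fixed sticky chain for reuse across tests.
fixture_chain <- function(k = 5, alpha = 0.5, rho = 0.35, seed = 99) {
  set.seed(seed)
  m <- random_transition_matrix(k, alpha)
  tr <- rho * diag(k) + (1 - rho) * m
  dimnames(tr) <- dimnames(m)
  tr
}

# Tiny corpus data frame used by corpus-module tests.
fixture_rows <- function() {
  data.frame(
    individual = "amy",
    sequence_id = c("s1", "s1", "s1", "s2", "s2"),
    collection_index = c(1L, 1L, 1L, 2L, 2L),
    order = c(1L, 2L, 3L, 1L, 2L),
    manipulation = c("Grasp", "Place", "Strike", "Grasp", "Eat"),
    object = c("Nut", "Nut", "Hammer", "Kernel", "Kernel"),
    stringsAsFactors = FALSE
  )
}
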