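test_that("Markov fitting reproduces hand-counted bigram ratios", {
  m <- fit_markov(token_stream(c("A", "A", "B", "A", "B")))
  expect_equal(m$transition["A", "A"], 1 / 3)
  expect_equal(m$transition["A", "B"], 2 / 3)
  expect_equal(m$transition["B", "A"], 1)
  expect_true(all(abs(rowSums(m$transition) - 1) < 1e-12))

  alt <- fit_markov(token_stream(rep(c("A", "B"), 10)))
  expect_equal(alt$period, 2L)
  expect_true(alt$irreducible)

  # A->B, B->C, C->A plus A->A: gcd of cycle lengths {1, 3} = 1
  m3 <- fit_markov(token_stream(c("A", "A", "B", "C", "A", "B", "C", "A")))
  expect_true(m3$irreducible)
  expect_equal(m3$period, 1L)

  # stream-final unique symbol gets a self-loop row, with a warning
  expect_warning(mz <- fit_markov(token_stream(c("A", "A", "Z"))),
                 "self-loop")
  expect_equal(mz$transition["Z", "Z"], 1)
  expect_true(all(abs(rowSums(mz$transition) - 1) < 1e-12))
})

test_that("structural flags match the brute-force oracle on random chains", {
  set.seed(77)
  n_checked <- 0
  for (rep in 1:150) {
    k <- sample(2:6, 1)
    # sparse random digraph; ensure every row has an outgoing edge
    adj <- matrix(runif(k * k) < 0.35, k, k)
    for (i in seq_len(k)) if (!any(adj[i, ])) adj[i, sample(k, 1)] <- TRUE
    tr <- adj / rowSums(adj)
    dimnames(tr) <- list(LETTERS[1:k], LETTERS[1:k])
    chain <- list(states = LETTERS[1:k], transition = tr,
                  irreducible = igraph::is_connected(
                    igraph::graph_from_adjacency_matrix(tr > 0,
                                                        mode = "directed"),
                    mode = "strong"),
                  period = midecay:::chain_period(tr > 0))
    expect_identical(chain$irreducible, oracle_irreducible(adj))
    expect_identical(chain$period, oracle_period(adj))
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 150)
})

test_that("simulation follows the chain and reproduces its statistics", {
  # deterministic alternator
  tr <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  chain <- fit_markov(token_stream(rep(c("A", "B"), 5)))
  sim <- simulate_stream(chain, 6, seed = 1)
  s <- stream_symbols(sim)
  expect_true(all(s[-1] != s[-6]))

  # identity chain: constant stream
  cst <- fit_markov(token_stream(c("A", "A", "A")))
  expect_equal(unique(stream_symbols(simulate_stream(cst, 10, seed = 2))), "A")

  # ergodic chain: long-run bigram frequencies near the true matrix
  tr <- fixture_chain(k = 5)
  chain <- list(states = rownames(tr), transition = tr, irreducible = TRUE,
                period = 1L, degenerate = FALSE,
                initial = rep(0.2, 5))
  class(chain) <- "markov_chain_model"
  sim <- simulate_stream(chain, 1e5, seed = 3)
  refit <- fit_markov(sim)
  expect_lt(max(abs(refit$transition - tr)), 0.01)

  # same seed -> identical stream
  expect_identical(simulate_stream(chain, 500, seed = 4)$codes,
                   simulate_stream(chain, 500, seed = 4)$codes)
})

test_that("stationary distributions solve pi = pi T", {
  tr <- fixture_chain(k = 4, seed = 123)
  chain <- list(states = rownames(tr), transition = tr, irreducible = TRUE,
                period = 1L)
  class(chain) <- "markov_chain_model"
  pi0 <- stationary_distribution(chain)
  expect_equal(sum(pi0), 1, tolerance = 1e-12)
  expect_equal(as.numeric(pi0 %*% tr), as.numeric(pi0), tolerance = 1e-10)
})

test_that("Garwood Poisson CIs match the chi-square construction", {
  ci <- poisson_exact_ci(rep(3, 100))
  expect_equal(ci$mean, 3)
  expect_equal(ci$lower, qchisq(0.025, 600) / 200, tolerance = 1e-12)
  expect_equal(ci$upper, qchisq(0.975, 602) / 200, tolerance = 1e-12)
  expect_equal(round(ci$lower, 2), 2.67)
  expect_equal(round(ci$upper, 2), 3.36)
  # observed value equal to the mean is inside the band
  expect_lte(ci$lower, 3); expect_gte(ci$upper, 3)
  z <- poisson_exact_ci(rep(0, 10))
  expect_equal(z$lower, 0)
})

test_that("null max-distance distributions separate structure from chance", {
  # iid chain: null maxima near zero, structured observed max is 'greater'
  k <- 6
  iid <- matrix(1 / k, k, k, dimnames = list(letters[1:k], letters[1:k]))
  chain <- list(states = letters[1:k], transition = iid, irreducible = TRUE,
                period = 1L, degenerate = FALSE,
                initial = rep(1 / k, k))
  class(chain) <- "markov_chain_model"
  nd <- null_max_distance(chain, corpus_length = 800, observed_max = 17,
                          n_sims = 15, d_max = 40, n_perm = 80, seed = 5)
  expect_lt(nd$mean, 5)
  expect_equal(nd$verdict, "greater")
  expect_equal(length(nd$maxima), 15)
  # observed inside the band -> not_greater
  nd2 <- null_max_distance(chain, corpus_length = 800,
                           observed_max = round(nd$mean),
                           n_sims = 15, d_max = 40, n_perm = 80, seed = 5)
  expect_equal(nd2$verdict, "not_greater")
})

test_that("corpus pooling concatenates individuals alphabetically", {
  df <- rbind(
    data.frame(individual = "zoe", sequence_id = "z1", collection_index = 1L,
               order = 1:2, manipulation = "grasp", object = "nut"),
    data.frame(individual = "amy", sequence_id = "a1", collection_index = 1L,
               order = 1:2, manipulation = "strike", object = "hammer")
  )
  corpora <- corpus_from_rows(df)
  pooled <- pool_corpora(corpora)
  expect_equal(stream_symbols(pooled),
               c("strike HAMMER", "strike HAMMER", "grasp NUT", "grasp NUT"))
  cond <- pool_corpora(corpora, condensed = TRUE)
  expect_equal(cond$N, 2L)
})

test_that("the community experiment tallies preferences consistently", {
  tr <- fixture_chain(k = 5, rho = 0.45, seed = 55)
  pooled <- gen_markov(1500, transition = tr, seed = 56)
  cs <- community_experiment(pooled, n_sequences = 8, sim_length = 600,
                             d_max = 60, n_perm = 100, seed = 57)
  expect_equal(nrow(cs$per_sequence), 8)
  expect_equal(cs$n_all_fitted, sum(cs$per_sequence$all_fitted))
  fitted <- cs$per_sequence[cs$per_sequence$all_fitted, ]
  expect_equal(unname(cs$counts["tie"]), sum(fitted$n_best > 1, na.rm = TRUE))
  expect_equal(sum(cs$counts[c("exponential", "power_law", "composite")]),
               sum(!is.na(fitted$sole_best)))
  if (cs$n_all_fitted > 0) {
    expect_equal(unname(cs$proportions["exponential"] +
                          cs$proportions["power_law"] +
                          cs$proportions["composite"] +
                          cs$proportions["tie"]), 1, tolerance = 1e-12)
  }
})
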