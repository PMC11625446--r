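test_that("generators are deterministic given spec and seed", {
  expect_identical(gen_markov(500, seed = 1)$codes,
                   gen_markov(500, seed = 1)$codes)
  expect_identical(gen_hierarchical(depth = 9, seed = 2)$codes,
                   gen_hierarchical(depth = 9, seed = 2)$codes)
  a <- gen_composite(seed = 3)
  b <- gen_composite(seed = 3)
  expect_identical(a$stream$codes, b$stream$codes)
  expect_identical(a$boundaries, b$boundaries)
  n1 <- gen_nutcracking_corpus(n_individuals = 1, n_tokens = 400, seed = 4)
  n2 <- gen_nutcracking_corpus(n_individuals = 1, n_tokens = 400, seed = 4)
  expect_identical(stream_symbols(n1[[1]]$stream),
                   stream_symbols(n2[[1]]$stream))
})

test_that("markov generator validates and embodies its chain", {
  expect_error(gen_markov(100, transition = matrix(c(0.5, 0.4, 0.4, 0.4), 2)),
               "simplex")
  # deterministic alternator
  tr <- matrix(c(0, 1, 1, 0), 2, 2, byrow = TRUE,
               dimnames = list(c("A", "B"), c("A", "B")))
  s <- stream_symbols(gen_markov(8, transition = tr, seed = 5))
  expect_true(all(s[-1] != s[-8]))
  # iid rows -> no adjusted MI beyond chance
  iid <- matrix(0.25, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  st <- gen_markov(2000, transition = iid, seed = 6)
  curve <- estimate_decay_curve(st, d_max = 30, n_perm = 100, seed = 7)
  expect_lt(max_dependency_distance(curve)$distance, 5)
})

test_that("deterministic substitution systems expand exactly", {
  th <- gen_hierarchical(depth = 3, rules = list(A = c("A", "B"),
                                                 B = c("B", "A")),
                         root = "A")
  expect_equal(paste(stream_symbols(th), collapse = ""), "ABBABAAB")
  # depth 1 is a single substitution
  d1 <- gen_hierarchical(depth = 1, rules = list(A = c("A", "B"),
                                                 B = c("B", "A")), root = "A")
  expect_equal(stream_symbols(d1), c("A", "B"))
  expect_error(gen_hierarchical(depth = 40, k = 2), "cap")
})

test_that("hierarchical streams carry long-range dependencies", {
  # adjusted MI stays positive across distant elements (chance level: half)
  hits <- 0
  for (s in 1:5) {
    st <- gen_hierarchical(depth = 11, seed = 100 + s, length = 2000)
    curve <- estimate_decay_curve(st, d_max = 60, n_perm = 120,
                                  seed = 200 + s)
    far <- curve[curve$d >= 30, ]
    if (mean(far$mi_adj > 0) >= 0.8) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("composite streams have the configured subroutine anatomy", {
  gc <- gen_composite(n_subroutines = 4, L_min = 5, L_max = 5, depth = 6,
                      seed = 11)
  expect_equal(unique(gc$lengths), 5L)
  expect_equal(gc$boundaries, seq(1, by = 5, length.out = 2^6))
  expect_equal(length(unique(gc$subroutine_ids)) <= 4, TRUE)
  # pure-hierarchy limit: unit-length subroutines
  g1 <- gen_composite(L_min = 1, L_max = 1, depth = 6, seed = 12)
  expect_true(all(g1$lengths == 1L))
  expect_warning(gen_composite(n_subroutines = 1, depth = 4, seed = 13),
                 "periodic")
  expect_error(gen_composite(n_subroutines = 0), "non-empty")
  expect_error(gen_composite(L_min = 3, L_max = 2), "length range")
})

test_that("emitted subroutine lengths follow the configured distribution", {
  gc <- gen_composite(L_min = 2, L_max = 8, depth = 9, seed = 14)
  obs <- table(factor(gc$lengths, levels = 2:8))
  p <- chisq.test(obs, p = rep(1 / 7, 7))$p.value
  expect_gt(p, 0.01)
})

test_that("the nut-cracking generator hits its statistical targets", {
  nc <- gen_nutcracking_corpus(n_individuals = 2, n_tokens = 5000,
                               n_sequences = 20, seed = 15)
  audit <- attr(nc, "audit")
  expect_true(all(abs(audit$realized_top5 - 0.63) < 0.03))
  # per-nut mean within 2 SE of target
  for (cp in nc) {
    summ <- summarize_corpus(cp)
    expect_lt(abs(summ$mean_per_nut_length - 22),
              2 * sqrt(22 / summ$nuts_cracked) + 2)
  }
  # zero repeat intensity: condensing is the identity
  nr <- gen_nutcracking_corpus(n_individuals = 1, n_tokens = 800,
                               repeat_intensity = 0, seed = 16)
  st <- nr[[1]]$stream
  expect_identical(condense(st)$codes, st$codes)
  expect_error(gen_nutcracking_corpus(top5_share = 1.2), "infeasible")
})
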