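test_that("action tokens normalize case, whitespace and reject empties", {
  expect_equal(action_token(" Grasp ", "nut"), "grasp NUT")
  expect_equal(action_token("STRIKE", " Hammer"), "strike HAMMER")
  expect_error(action_token("", "nut"), "non-empty")
})

test_that("corpus loading builds per-individual streams in collection order", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- fixture_rows()
  # write sequence 2 rows before sequence 1: file order must not matter
  utils::write.table(df[c(4, 5, 1, 2, 3), ], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  corpora <- load_corpus(path)
  expect_named(corpora, "amy")
  cp <- corpora$amy
  expect_equal(cp$stream$N, 5L)
  expect_equal(stream_symbols(cp$stream),
               c("grasp NUT", "place NUT", "strike HAMMER",
                 "grasp KERNEL", "eat KERNEL"))
  expect_equal(length(unique(cp$rows$sequence_id)), 2L)
})

test_that("malformed inputs are rejected with diagnostics", {
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- fixture_rows()
  df$object[2] <- ""
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_corpus(path), "row")

  df2 <- fixture_rows()
  df2$order[2] <- 1L
  path2 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(df2, path2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(load_corpus(path2), "duplicate")

  path3 <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(fixture_rows()[, -6], path3, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_error(load_corpus(path3), "missing column")

  path4 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("individual", "sequence_id", "collection_index",
                     "order", "manipulation", "object"), collapse = "\t"),
             path4)
  expect_error(load_corpus(path4), "empty")
})

test_that("condensing collapses runs, preserves order, and is idempotent", {
  s <- token_stream(rep("strike HAMMER", 3))
  expect_equal(stream_symbols(condense(s)), "strike HAMMER")
  s2 <- token_stream(c("A", "B", "A"))
  expect_equal(stream_symbols(condense(s2)), c("A", "B", "A"))
  s3 <- token_stream(c("A", "A", "B", "B", "A"))
  expect_equal(stream_symbols(condense(s3)), c("A", "B", "A"))

  set.seed(7)
  for (i in 1:25) {
    s <- token_stream(sample(LETTERS[1:4], 60, replace = TRUE))
    c1 <- condense(s)
    expect_false(any(c1$codes[-1] == c1$codes[-c1$N]))
    expect_identical(condense(c1)$codes, c1$codes)
    expect_lte(c1$N, s$N)
    if (!any(s$codes[-1] == s$codes[-s$N])) expect_identical(c1$codes, s$codes)
  }
})

test_that("corpus summaries reproduce Poisson-approximation arithmetic", {
  # published count pairs and their printed mean +/- SE cells
  f <- poisson_mean_se(1368, 21)
  expect_equal(round(f$mean, 1), 65.1)
  expect_equal(f$se, 1.8, tolerance = 0.05)
  t <- poisson_mean_se(1940, 15)
  expect_equal(round(t$mean, 1), 129.3)
  expect_equal(t$se, 2.9, tolerance = 0.05)
  s <- poisson_mean_se(9, 1)
  expect_equal(s$mean, 9)
  expect_equal(s$se, 3.0)

  df <- fixture_rows()
  df$nut_episode <- c("n1", "n1", "n1", "n2", "n2")
  cp <- corpus_from_rows(df)$amy
  summ <- summarize_corpus(cp)
  expect_equal(summ$n_sequences, 2L)
  expect_equal(summ$n_elements, 5L)
  expect_equal(summ$mean_seq_length, 2.5)
  expect_equal(summ$se_seq_length, sqrt(2.5 / 2))
  expect_equal(summ$nuts_cracked, 2L)
  expect_equal(summ$mean_per_nut_length, 2.5)

  # per-nut stats flagged unavailable (NA), not zero, without annotations
  summ2 <- summarize_corpus(corpus_from_rows(fixture_rows())$amy)
  expect_true(is.na(summ2$mean_per_nut_length))
  expect_true(is.na(summ2$nuts_cracked))
})

test_that("action-type profiles count, sum to one, and filter", {
  p <- action_type_profile(token_stream(c("A", "A", "B")))
  expect_equal(p$frequency[p$symbol == "A"], 2 / 3)
  expect_equal(sum(p$frequency), 1)
  p2 <- action_type_profile(token_stream(rep(c("A", "B", "C", "D"), 100)))
  expect_true(all(p2$frequency == 0.25))
  p3 <- action_type_profile(
    token_stream(c(rep("A", 5), rep("B", 4), "C")), threshold = 0.3)
  expect_setequal(p3$symbol, c("A", "B"))
})

test_that("corpora round-trip through write_corpus/load_corpus", {
  df <- fixture_rows()
  corpora <- corpus_from_rows(df)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_corpus(corpora, path)
  back <- load_corpus(path)
  expect_identical(stream_symbols(back$amy$stream),
                   stream_symbols(corpora$amy$stream))
})
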