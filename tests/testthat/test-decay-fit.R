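test_that("noise-free curves are recovered exactly by their own family", {
  x <- 1:20
  fe <- fit_decay_model(data.frame(d = x, mi_adj = 1.0 * exp(-0.5 * x)),
                        "exponential")
  expect_true(fe$converged)
  expect_equal(unname(fe$coefficients), c(1.0, 0.5), tolerance = 1e-6)
  expect_lt(fe$RSS, 1e-10)

  fp <- fit_decay_model(data.frame(d = x, mi_adj = 2.0 * x^(-0.8)),
                        "power_law")
  expect_equal(unname(fp$coefficients), c(2.0, -0.8), tolerance = 1e-6)
  expect_lt(fp$RSS, 1e-10)

  x2 <- 1:30
  y <- 1.5 * exp(-0.9 * x2) + 0.3 * x2^(-0.6)
  fc <- fit_decay_model(data.frame(d = x2, mi_adj = y), "composite")
  expect_equal(unname(fc$coefficients[c("a", "b", "c", "p")]),
               c(1.5, 0.9, 0.3, -0.6), tolerance = 0.01)
  expect_lt(fc$RSS, 1e-10)
  cmp <- compare_models(list(
    fit_decay_model(data.frame(d = x2, mi_adj = y), "exponential"),
    fit_decay_model(data.frame(d = x2, mi_adj = y), "power_law"), fc))
  expect_equal(cmp$sole_best, "composite")
})

test_that("fitted coefficients respect the decay-toward-zero bounds", {
  set.seed(31)
  y <- 0.8 * exp(-0.4 * (1:15)) + rnorm(15, sd = 0.02)
  for (fam in c("exponential", "power_law", "composite")) {
    f <- fit_decay_model(data.frame(d = 1:15, mi_adj = y), fam)
    if (!f$converged) next
    co <- f$coefficients
    expect_gte(co[["a"]], 0)
    if (fam == "exponential") expect_gte(co[["b"]], 0)
    if (fam == "power_law") expect_lte(co[["b"]], 0)
    if (fam == "composite") {
      expect_gte(co[["b"]], 0); expect_gte(co[["c"]], 0)
      expect_lte(co[["p"]], 0)
    }
  }
})

test_that("multi-start fitting is deterministic", {
  set.seed(17)
  pts <- data.frame(d = 1:25, mi_adj = 1.2 * exp(-0.3 * (1:25)) +
                      rnorm(25, sd = 0.01))
  f1 <- fit_decay_model(pts, "composite")
  f2 <- fit_decay_model(pts, "composite")
  expect_identical(f1$coefficients, f2$coefficients)
})

test_that("likelihood and AICc follow the Gaussian least-squares form", {
  # K counts the error variance: 3 for two-coefficient families, 5 composite
  f <- list(family = "exponential", RSS = 10, n_points = 10L, K = 3L,
            converged = TRUE)
  class(f) <- "decay_model_fit"
  f <- gaussian_ll_aicc(f)
  expect_equal(f$LL, -(10 / 2) * (log(2 * pi) + 1), tolerance = 1e-10)
  expect_equal(round(f$LL, 2), -14.19)
  expect_equal(f$AICc, 2 * 3 - 2 * f$LL + 2 * 3 * 4 / (10 - 3 - 1))
  expect_equal(fit_decay_model(
    data.frame(d = 1:10, mi_adj = exp(-0.5 * (1:10))), "exponential")$K, 3L)
  expect_equal(fit_decay_model(
    data.frame(d = 1:10, mi_adj = exp(-0.5 * (1:10)) + 0.2 * (1:10)^-0.5),
    "composite")$K, 5L)
  # AICc -> AIC for large n
  g <- list(family = "exponential", RSS = 1e5, n_points = 1e5L, K = 3L,
            converged = TRUE)
  class(g) <- "decay_model_fit"
  g <- gaussian_ll_aicc(g)
  aic <- 2 * 3 - 2 * g$LL
  expect_lt(abs(g$AICc - aic), 1e-3)
  # undefined when n <= K + 1
  h <- list(family = "exponential", RSS = 1, n_points = 4L, K = 3L,
            converged = TRUE)
  class(h) <- "decay_model_fit"
  expect_error(gaussian_ll_aicc(h), "undefined")
})

test_that("too few points raises a fit-infeasible error naming the family", {
  expect_error(fit_decay_model(data.frame(d = 1:5, mi_adj = exp(-(1:5))),
                               "composite"), "composite")
})

test_that("Akaike weights reproduce published model-selection rows", {
  w1 <- akaike_weights(c(0.0, 5.3, 23.3))
  expect_equal(round(w1, 2), c(0.93, 0.07, 0.00))
  w2 <- akaike_weights(c(0.0, 8.2, 19.4))
  expect_equal(round(w2[1], 2), 0.98)
  expect_equal(sum(w1), 1, tolerance = 1e-12)
  # order invariance
  set.seed(13)
  d <- runif(5, 0, 30)
  perm <- sample(5)
  expect_equal(akaike_weights(d)[perm], akaike_weights(d[perm]),
               tolerance = 1e-12)
})

test_that("model comparison flags sole winners and competing sets", {
  mk <- function(fam, aicc) {
    f <- list(family = fam, RSS = 1, n_points = 20L,
              K = if (fam == "composite") 5L else 3L, LL = 0,
              AICc = aicc, converged = TRUE)
    class(f) <- "decay_model_fit"
    f
  }
  cmp <- compare_models(list(mk("exponential", -40), mk("power_law", -20),
                             mk("composite", -45)))
  expect_equal(cmp$sole_best, "composite")
  expect_equal(cmp$table$family[1], "composite")
  expect_equal(sum(cmp$table$weight), 1, tolerance = 1e-12)
  cmp2 <- compare_models(list(mk("exponential", -44.2), mk("composite", -45)))
  expect_true(is.na(cmp2$sole_best))
  expect_setequal(cmp2$best_set, c("exponential", "composite"))
  cmp3 <- compare_models(list(mk("power_law", -10)))
  expect_equal(cmp3$sole_best, "power_law")
  expect_equal(cmp3$table$weight, 1)
  bad <- mk("exponential", NA_real_)
  bad$converged <- FALSE
  expect_error(compare_models(list(bad)), "no converged")
})
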