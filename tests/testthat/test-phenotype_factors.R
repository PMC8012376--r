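test_that("correlation matrix is validated and matches implied correlations", {
  x <- cbind(a = rnorm(50), b = rnorm(50))
  x <- cbind(x, dup = x[, "a"])
  R <- correlation_matrix(x)
  expect_equal(R["a", "dup"], 1.0)
  expect_identical(R, t(R))
  expect_equal(unname(diag(R)), rep(1, 3))
  expect_error(correlation_matrix(cbind(a = rnorm(10), flat = rep(2, 10))),
               "flat", class = "neurocausal_validation_error")
  # two independent columns at n = 1e4
  set.seed(8)
  xi <- cbind(u = rnorm(10000), v = rnorm(10000))
  expect_lt(abs(correlation_matrix(xi)["u", "v"]), 0.05)
  # battery correlations track Lambda Phi Lambda' within Monte-Carlo error
  spec <- block_factor_spec(2, 4, loading = 0.7)
  xb <- simulate_factor_battery(spec, 10000, seed = 12)
  implied <- spec$loadings %*% spec$phi %*% t(spec$loadings) +
    diag(spec$uniquenesses)
  expect_equal(unname(correlation_matrix(xb)), unname(implied),
               tolerance = 3 / sqrt(10000) * 5)
})

test_that("eigenvalues of the observed correlation matrix sum to p", {
  spec <- block_factor_spec(3, 6, loading = 0.6)
  x <- simulate_factor_battery(spec, 400, seed = 2)
  pa <- parallel_analysis(x, n_perm = 20, seed = 3)
  expect_equal(sum(pa$observed), ncol(x), tolerance = 1e-8)
  expect_true(all(diff(pa$observed) <= 1e-12))
})

test_that("parallel analysis recovers the block design and stays monotone", {
  x3 <- simulate_factor_battery(block_factor_spec(3, 7, loading = 0.8),
                                1000, seed = 42)
  expect_identical(parallel_analysis(x3, n_perm = 100, seed = 7)$k, 3L)
  # normal-reference null agrees on a strong design
  expect_identical(parallel_analysis(x3, n_perm = 100, seed = 7,
                                     null = "normal")$k, 3L)
  # selected k never decreases as loadings grow (fixed seeds)
  ks <- vapply(c(0.3, 0.5, 0.7), function(l) {
    xb <- simulate_factor_battery(block_factor_spec(3, 7, loading = l),
                                  1000, seed = 42)
    parallel_analysis(xb, n_perm = 60, seed = 7)$k
  }, integer(1))
  expect_true(all(diff(ks) >= 0))
  expect_error(parallel_analysis(x3, n_perm = 0),
               class = "neurocausal_validation_error")
})

test_that("ML extraction recovers a one-factor structure", {
  spec <- factor_spec(matrix(0.75, 9, 1,
                             dimnames = list(sprintf("it%d", 1:9), "F1")))
  x <- simulate_factor_battery(spec, 2000, seed = 77)
  m <- fit_efa(x, 1)
  expect_gt(loading_congruence(spec$loadings, m$loadings), 0.98)
  expect_lt(m$rmsea, 0.03)
  expect_equal(nrow(m$variance), 1L)
  expect_equal(m$variance$cumulative, 1.0)
})

test_that("EM solution agrees with the factanal oracle", {
  spec <- block_factor_spec(3, 7, loading = 0.8)
  x <- simulate_factor_battery(spec, 1000, seed = 42)
  m <- fit_efa(x, 3)
  fa <- stats::factanal(covmat = correlation_matrix(x), factors = 3,
                        n.obs = 1000, rotation = "none")
  expect_equal(sort(unname(m$uniquenesses)), sort(unname(fa$uniquenesses)),
               tolerance = 1e-4)
})

test_that("communality plus uniqueness is one per standardized item", {
  spec <- block_factor_spec(3, 7, loading = 0.8)
  x <- simulate_factor_battery(spec, 1000, seed = 42)
  m <- fit_efa(x, 3)
  comm <- diag(m$loadings %*% m$phi %*% t(m$loadings))
  expect_equal(unname(comm + m$uniquenesses), rep(1, 21), tolerance = 1e-6)
})

test_that("oblimin rotation preserves chi-square, RMSEA and TLI", {
  spec <- block_factor_spec(3, 6, loading = 0.7,
                            phi = 0.3 + 0.7 * diag(3))
  x <- simulate_factor_battery(spec, 800, seed = 13)
  m_rot <- fit_efa(x, 3, rotate = "oblimin")
  m_raw <- fit_efa(x, 3, rotate = "none")
  expect_equal(m_rot$chisq, m_raw$chisq, tolerance = 1e-8)
  expect_equal(m_rot$rmsea, m_raw$rmsea, tolerance = 1e-8)
  expect_equal(m_rot$tli, m_raw$tli, tolerance = 1e-8)
  # rotation recovers the oblique factor correlation
  expect_equal(mean(m_rot$phi[upper.tri(m_rot$phi)]), 0.3, tolerance = 0.12)
})

test_that("orthogonal blocks keep near-zero factor correlations", {
  spec <- block_factor_spec(2, 8, loading = 0.8)
  x <- simulate_factor_battery(spec, 2000, seed = 19)
  m <- fit_efa(x, 2)
  expect_lt(abs(m$phi[1, 2]), 0.1)
  # two equal orthogonal factors each explain half the common variance
  expect_equal(m$variance$proportion, c(0.5, 0.5), tolerance = 0.05)
})

test_that("variance accounting matches the generating model", {
  L <- cbind(F1 = c(rep(0.8, 4), rep(0, 4), rep(0, 4)),
             F2 = c(rep(0, 4), rep(0.6, 4), rep(0, 4)),
             F3 = c(rep(0, 4), rep(0, 4), rep(0.4, 4)))
  rownames(L) <- sprintf("v%02d", 1:12)
  truth <- colSums(L^2) / sum(L^2)
  spec <- factor_spec(L)
  x <- simulate_factor_battery(spec, 4000, seed = 99)
  m <- fit_efa(x, 3)
  expect_equal(sum(m$variance$proportion), 1, tolerance = 1e-10)
  expect_equal(m$variance$proportion, unname(sort(truth, decreasing = TRUE)),
               tolerance = 0.05)
})

test_that("regression scores behave as the closed form and recover truth", {
  # equal loadings on one factor: scores proportional to row means
  spec <- factor_spec(matrix(0.7, 8, 1,
                             dimnames = list(sprintf("q%d", 1:8), "F1")))
  x <- simulate_factor_battery(spec, 500, seed = 3)
  m <- fit_efa(x, 1)
  sc <- factor_scores(m, x)
  rm_std <- rowMeans(scale(x))
  # exact proportionality holds for the model-implied correlation matrix;
  # the sample matrix deviates slightly from exchangeability
  expect_gt(abs(cor(sc[, 1], rm_std)), 0.999)
  # permuting subjects permutes scores identically
  perm <- sample(nrow(x))
  sc_perm <- factor_scores(m, x[perm, ])
  expect_equal(unname(sc_perm), unname(sc[perm, , drop = FALSE]),
               tolerance = 1e-8)
  # recovery of simulated factors at strong loadings
  sim <- simulate_factor_battery_with_truth(block_factor_spec(3, 7, 0.8),
                                            2000, seed = 9)
  m3 <- fit_efa(sim$items, 3)
  s3 <- factor_scores(m3, sim$items)
  best <- apply(abs(cor(s3, sim$factors)), 2, max)
  expect_true(all(best > 0.9))
  # Bartlett alternative exists and correlates with regression scores
  s3b <- factor_scores(m3, sim$items, method = "bartlett")
  expect_true(all(diag(abs(cor(s3, s3b))) > 0.95))
  expect_error(factor_scores(m3, sim$items[, rev(colnames(sim$items))]),
               class = "neurocausal_validation_error")
})

test_that("k above the Ledermann bound is rejected", {
  x <- simulate_factor_battery(block_factor_spec(2, 3), 200, seed = 1)
  expect_error(fit_efa(x, 4), "Ledermann",
               class = "neurocausal_validation_error")
})
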