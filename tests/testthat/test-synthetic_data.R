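test_that("linear SEM simulation matches the closed-form implied covariance", {
  # chain X -> Y -> Z with unit weights and unit noise
  g <- ground_truth_graph(c("X", "Y", "Z"),
                          data.frame(from = c("X", "Y"), to = c("Y", "Z"),
                                     weight = c(1, 1)))
  n <- 10000
  x <- simulate_linear_sem(g, n, seed = 11)
  S_true <- implied_covariance(g)
  S_hat <- crossprod(scale(x, scale = FALSE)) / n
  # entrywise within 3 x Monte-Carlo SE; for Gaussian data
  # var(s_ij) ~ (sigma_ii sigma_jj + sigma_ij^2) / n
  mc_se <- sqrt((outer(diag(S_true), diag(S_true)) + S_true^2) / n)
  expect_true(all(abs(S_hat - S_true) < 3 * mc_se))
})

test_that("zero-weight graphs give mutually independent columns", {
  g <- ground_truth_graph(c("A", "B", "C"),
                          data.frame(from = "A", to = "B", weight = 0))
  x <- simulate_linear_sem(g, 10000, seed = 2)
  r <- cor(x)
  expect_true(all(abs(r[upper.tri(r)]) < 0.05))
})

test_that("a hidden common cause induces the predicted marginal correlation", {
  # X <- L -> Y, weights 1, unit noise: corr(X, Y) = 1/2
  g <- ground_truth_graph(c("X", "Y", "L"),
                          data.frame(from = c("L", "L"), to = c("X", "Y"),
                                     weight = c(1, 1)),
                          latent = "L")
  expect_equal(cov2cor(implied_covariance(g))["X", "Y"], 0.5)
  x <- simulate_linear_sem(g, 10000, seed = 3)
  expect_named(as.data.frame(x), c("X", "Y")) # latent column dropped
  expect_equal(cor(x)["X", "Y"], 0.5, tolerance = 0.05)
})

test_that("cycles and invalid noise variances are rejected", {
  expect_error(
    ground_truth_graph(c("X", "Y"),
                       data.frame(from = c("X", "Y"), to = c("Y", "X"),
                                  weight = c(1, 1))),
    class = "neurocausal_structural_error")
  expect_error(
    ground_truth_graph("X", noise_var = c(X = 0)),
    class = "neurocausal_validation_error")
})

test_that("generators are byte-deterministic given the seed", {
  g <- fig1_like_graph()
  expect_identical(simulate_linear_sem(g, 100, seed = 9),
                   simulate_linear_sem(g, 100, seed = 9))
  spec <- block_factor_spec(3, 5)
  expect_identical(simulate_factor_battery(spec, 50, seed = 5),
                   simulate_factor_battery(spec, 50, seed = 5))
  s1 <- make_benchmark_suite(7, n = 50)
  s2 <- make_benchmark_suite(7, n = 50)
  expect_identical(s1$fig1_like$data, s2$fig1_like$data)
})

test_that("factor battery moments follow Lambda Phi Lambda' + Psi", {
  spec <- block_factor_spec(3, 5, loading = 0.8)
  x <- simulate_factor_battery(spec, 2000, seed = 21)
  r <- cor(x)
  within_pairs <- r[1:5, 1:5][upper.tri(diag(5))]
  cross_pairs <- r[1:5, 6:10]
  expect_equal(mean(within_pairs), 0.64, tolerance = 0.04)
  expect_lt(max(abs(cross_pairs)), 0.1)
  # all-zero loadings: independent items
  spec0 <- factor_spec(matrix(0, 6, 1), uniquenesses = rep(1, 6))
  x0 <- simulate_factor_battery(spec0, 5000, seed = 1)
  r0 <- cor(x0)
  expect_lt(max(abs(r0[upper.tri(r0)])), 0.06)
})

test_that("parcel time-series blocks reproduce the target Fisher z", {
  part <- setNames(rep(c("net1", "net2"), each = 5),
                   paste0("p", 1:10))
  spec <- timeseries_spec(part, within_r = 0.5, between_r = 0,
                          timepoints = 1200)
  runs <- simulate_parcel_timeseries(spec, n_subjects = 20, seed = 31)
  expect_length(runs, 20)
  expect_identical(dim(runs[[1]]), c(10L, 1200L))
  prof <- t(vapply(runs, within_network_connectivity, numeric(2),
                   partition = part))
  # mean z targets atanh(0.5) = 0.549; SE of a single z is about
  # 1/sqrt(T-3), and averaging 10 correlated pairs over 20 subjects
  # shrinks it further; 3 SE of the per-network subject mean
  se <- 1 / sqrt(1200 - 3) / sqrt(20)
  expect_equal(unname(colMeans(prof)), rep(atanh(0.5), 2),
               tolerance = 3 * se * 5)
  # null case: r = 0 gives mean z near 0
  spec0 <- timeseries_spec(part, within_r = 0, timepoints = 1200)
  runs0 <- simulate_parcel_timeseries(spec0, 10, seed = 5)
  prof0 <- t(vapply(runs0, within_network_connectivity, numeric(2),
                    partition = part))
  expect_lt(max(abs(colMeans(prof0))), 0.05)
})

test_that("symptom-count discretization counts thresholds below the latent", {
  th <- c(-1, 0, 1, 2, 3)
  expect_identical(simulate_symptom_counts(rep(-5, 4), th), rep(0L, 4))
  expect_identical(simulate_symptom_counts(rep(10, 2), th), rep(5L, 2))
  expect_identical(simulate_symptom_counts(c(-0.5, 0.5, 2.5), th),
                   c(1L, 2L, 4L))
  expect_error(simulate_symptom_counts(0, c(1, 1, 2, 3, 4)),
               class = "neurocausal_validation_error")
  # uniform latent over the threshold span: category frequencies track
  # the threshold spacing
  set.seed(4)
  u <- runif(20000, -2, 4)
  counts <- tabulate(simulate_symptom_counts(u, th) + 1L, 6)
  probs <- diff(c(-2, th, 4)) / 6
  expect_equal(counts / 20000, probs, tolerance = 0.02)
})

test_that("benchmark suite exposes the documented scenarios", {
  suite <- make_benchmark_suite(3, n = 200)
  expect_true(all(c("collider", "common_cause", "chain_forward",
                    "chain_backward", "hidden_confounder", "fig1_like") %in%
                    names(suite)))
  expect_gte(length(suite), 6)
  fig1 <- suite$fig1_like
  expect_identical(ncol(fig1$data), 31L)
  expect_identical(nrow(fig1$data), 200L)
  # unit-variance standardization of the generative model
  expect_equal(unname(diag(implied_covariance(fig1$graph))), rep(1, 31),
               tolerance = 1e-8)
  # severity's only cause is the externalizing node
  sev <- fig1$graph$edges[fig1$graph$edges$to == "aud_severity", ]
  expect_identical(sev$from, "externalizing")
})

test_that("collider scenario shows marginal independence, conditional dependence", {
  d <- bench5000()$collider$data
  marg <- fisher_z_ci_test(d, "X", "Y", character(), alpha = 0.01)
  cond <- fisher_z_ci_test(d, "X", "Y", "Z", alpha = 0.01)
  expect_true(marg$independent)
  expect_lt(cond$p_value, 0.01)
})

test_that("ground-truth graphs round-trip through the edge-list format", {
  g <- fig1_like_graph()
  path <- withr::local_tempfile(fileext = ".txt")
  write_ground_truth_graph(g, path)
  reread <- read_pag(path)
  expect_identical(reread$nodes, g$nodes)
  expect_identical(nrow(graph_edges(reread)), nrow(g$edges))
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(side$edges$weight, g$edges$weight)
})
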