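test_that("RMSEA and TLI follow their defining formulas", {
  expect_identical(rmsea(10, 10, 500), 0)
  expect_equal(rmsea(20, 10, 101), 0.1)
  expect_true(rmsea(30, 10, 101) > rmsea(25, 10, 101))
  expect_error(rmsea(5, 0, 100), class = "neurocausal_domain_error")
  expect_equal(tli(20, 20, 500, 25), 1)
  expect_equal(tli(40, 20, 40, 20), 0)
  expect_equal(tli(30, 20, 500, 25), (20 - 1.5) / 19)
  expect_error(tli(10, 10, 30, 30), class = "neurocausal_domain_error")
})

test_that("PAG edges translate to SEM elements by the documented rules", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("nodes: A B C D E",
               "A --> B", "B o-> C", "C <-> D", "D o-o E"), path)
  spec <- pag_to_sem_spec(read_pag(path))
  expect_identical(nrow(spec$regressions), 2L) # -->, o->
  expect_identical(nrow(spec$covariances), 2L) # <->, o-o
  expect_identical(nrow(spec$log), 4L)
  expect_true(any(grepl("circle as tail", spec$log$rule)))
  # o-o may be dropped instead
  spec2 <- pag_to_sem_spec(read_pag(path), drop_circle_circle = TRUE)
  expect_identical(nrow(spec2$covariances), 1L)
  # single bidirected edge: one covariance, no regressions
  writeLines(c("nodes: X Y", "X <-> Y"), path)
  spec3 <- pag_to_sem_spec(read_pag(path))
  expect_identical(nrow(spec3$regressions), 0L)
  expect_identical(nrow(spec3$covariances), 1L)
  # cyclic translation errors, naming the cycle
  writeLines(c("nodes: X Y Z", "X --> Y", "Y --> Z", "Z --> X"), path)
  expect_error(pag_to_sem_spec(read_pag(path)), "X -> Y -> Z -> X",
               class = "neurocausal_structural_error")
  spec4 <- pag_to_sem_spec(read_pag(path), on_cycle = "covariance")
  expect_null(neurocausal:::find_regression_cycle(spec4))
})

test_that("SEM recovers the parameters of the spec that generated the data", {
  g <- ground_truth_graph(
    c("A", "B", "C", "D"),
    data.frame(from = c("A", "B", "C"), to = c("B", "C", "D"),
               weight = c(0.6, 0.5, 0.4)))
  d <- simulate_linear_sem(g, 5000, seed = 202)
  spec <- sem_spec(colnames(d),
                   regressions = data.frame(
                     child = c("B", "C", "D"),
                     parent = c("A", "B", "C")))
  fit <- fit_sem(spec, d)
  expect_true(fit$admissible)
  truth_std <- c(0.6 / sqrt(0.36 + 1),
                 0.5 * sqrt(1.36) / sqrt(0.25 * 1.36 + 1),
                 0.4 * sqrt(0.25 * 1.36 + 1) / sqrt(0.16 * (0.25 * 1.36 + 1) + 1))
  est <- fit$edges[fit$edges$type == "regression", ]
  expect_equal(est$std_weight, truth_std, tolerance = 0.05)
  expect_lt(fit$rmsea, 0.03)
  # simulate from the fitted spec and refit: estimates land within 3 SE
  # of the generating (fitted) values
  d2 <- simulate_sem_result(fit, 5000, seed = 303)
  refit <- fit_sem(spec, d2)
  expect_true(all(abs(refit$edges$estimate - fit$edges$estimate) <
                    3 * refit$edges$se))
  expect_lt(refit$rmsea, 0.02)
})

test_that("a saturated recursive model fits exactly with zero df", {
  set.seed(33)
  d <- cbind(X = rnorm(300))
  d <- cbind(d, Y = 0.5 * d[, 1] + rnorm(300))
  d <- cbind(d, Z = 0.4 * d[, 2] + rnorm(300))
  spec <- sem_spec(colnames(d),
                   regressions = data.frame(
                     child = c("Y", "Z", "Z"),
                     parent = c("X", "X", "Y")))
  fit <- fit_sem(spec, d)
  expect_identical(fit$df, 0)
  expect_lt(fit$chisq, 1e-4)
})

test_that("omitting a strong edge inflates chi-square and RMSEA", {
  g <- ground_truth_graph(
    c("A", "B", "C"),
    data.frame(from = c("A", "B", "A"), to = c("B", "C", "C"),
               weight = c(0.6, 0.5, 0.5)))
  d <- simulate_linear_sem(g, 5000, seed = 77)
  spec <- sem_spec(colnames(d),
                   regressions = data.frame(child = c("B", "C"),
                                            parent = c("A", "B")))
  fit <- fit_sem(spec, d)
  expect_gt(fit$chisq, 10 * fit$df)
  expect_gt(fit$rmsea, 0.05)
})

test_that("standardized weights are invariant to column rescaling", {
  g <- ground_truth_graph(
    c("A", "B", "C"),
    data.frame(from = c("A", "B"), to = c("B", "C"), weight = c(0.5, 0.5)))
  d <- simulate_linear_sem(g, 800, seed = 55)
  spec <- sem_spec(colnames(d),
                   regressions = data.frame(child = c("B", "C"),
                                            parent = c("A", "B")))
  f1 <- fit_sem(spec, d)
  d2 <- d
  d2[, "B"] <- d2[, "B"] * 37
  f2 <- fit_sem(spec, d2)
  expect_equal(f1$edges$std_weight, f2$edges$std_weight, tolerance = 1e-6)
  expect_equal(f1$chisq, f2$chisq, tolerance = 1e-6)
})

test_that("a fixed spec refits on new data and improves with n", {
  g <- ground_truth_graph(
    c("A", "B", "C"),
    data.frame(from = c("A", "B"), to = c("B", "C"), weight = c(0.5, 0.4)))
  spec <- sem_spec(c("A", "B", "C"),
                   regressions = data.frame(child = c("B", "C"),
                                            parent = c("A", "B")))
  fits <- lapply(c(500, 5000), function(n) {
    fit_sem(spec, simulate_linear_sem(g, n, seed = n))
  })
  # replication-style refit on alternately generated data just works
  expect_identical(fits[[1]]$n, 500L)
  expect_identical(fits[[2]]$n, 5000L)
  expect_lte(fits[[2]]$rmsea, fits[[1]]$rmsea + 0.01)
  expect_gte(fits[[2]]$tli + 0.01, fits[[1]]$tli)
  expect_lt(fits[[2]]$rmsea, 0.03)
  expect_gt(fits[[2]]$tli, 0.97)
})
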