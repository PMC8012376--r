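# Score -----------------------------------------------------------------

test_that("local BIC behaves as the closed forms predict", {
  set.seed(5)
  n <- 1000
  x <- rnorm(n)
  y_ind <- rnorm(n)
  d_ind <- cbind(X = x, Y = y_ind)
  # independent pair: penalty dominates the near-zero fit gain
  gain <- sem_bic_local_score(d_ind, "Y", "X") -
    sem_bic_local_score(d_ind, "Y", character())
  expect_lt(gain, 0)
  # Y = X + noise with R^2 = 0.5: expected gain -n log(0.5) - c log(n)
  y_dep <- x + rnorm(n)
  d_dep <- cbind(X = x, Y = y_dep)
  gain2 <- sem_bic_local_score(d_dep, "Y", "X") -
    sem_bic_local_score(d_dep, "Y", character())
  expect_equal(gain2, -n * log(0.5) - 2 * log(n), tolerance = 0.1 * n * 0.05)
  expect_gt(gain2, 0)
})

test_that("Markov-equivalent DAGs score identically (score equivalence)", {
  set.seed(6)
  x <- rnorm(2000)
  y <- 0.8 * x + rnorm(2000)
  d <- cbind(X = x, Y = y)
  s_xy <- sem_bic_local_score(d, "X", character()) +
    sem_bic_local_score(d, "Y", "X")
  s_yx <- sem_bic_local_score(d, "Y", character()) +
    sem_bic_local_score(d, "X", "Y")
  expect_equal(s_xy, s_yx, tolerance = 1e-6)
})

test_that("graph score decomposes as the sum of local scores", {
  suite <- make_benchmark_suite(2, n = 400)
  d <- suite$fig1_like$data[, 1:8]
  set.seed(9)
  for (rep in 1:5) {
    # random DAG over 8 nodes via a random ordering
    ord <- sample(colnames(d))
    edges <- NULL
    amat <- neurocausal:::mg_new(colnames(d))
    for (i in 2:length(ord)) {
      pa <- ord[seq_len(i - 1)][runif(i - 1) < 0.3]
      for (p_ in pa) amat <- neurocausal:::mg_add_directed(
        amat, match(p_, colnames(d)), match(ord[i], colnames(d)))
    }
    total <- dag_total_score(d, amat)
    by_hand <- sum(vapply(colnames(d), function(v) {
      pa <- colnames(d)[neurocausal:::mg_parents(amat, match(v, colnames(d)))]
      sem_bic_local_score(d, v, pa)
    }, numeric(1)))
    expect_equal(total, by_hand, tolerance = 1e-9)
  }
})

test_that("collinear parents are reported as a singular design", {
  set.seed(11)
  x <- rnorm(100)
  d <- cbind(A = x, B = 2 * x, Y = rnorm(100))
  expect_error(sem_bic_local_score(d, "Y", c("A", "B")),
               class = "neurocausal_validation_error")
})

# CI test ---------------------------------------------------------------

test_that("Fisher-z test holds its level and detects collider dependence", {
  hits <- vapply(1:100, function(s) {
    set.seed(1000 + s)
    d <- cbind(X = rnorm(1000), Y = rnorm(1000))
    fisher_z_ci_test(d, "X", "Y", character(), alpha = 0.01)$independent
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  d <- bench5000()$collider$data
  expect_true(fisher_z_ci_test(d, "X", "Y")$independent)
  expect_lt(fisher_z_ci_test(d, "X", "Y", "Z")$p_value, 0.01)
  dch <- bench5000()$chain_forward$data
  expect_true(fisher_z_ci_test(dch, "X", "Y", "Z")$independent)
  expect_error(fisher_z_ci_test(d, "X", "Y", "X"),
               class = "neurocausal_validation_error")
})

# Meek rules ------------------------------------------------------------

test_that("Meek closure orients forced edges and is idempotent", {
  # R1: X --> Z, Z -- Y, X and Y nonadjacent orients Z --> Y
  amat <- neurocausal:::mg_new(c("X", "Y", "Z"))
  amat <- neurocausal:::mg_add_directed(amat, 1, 3)
  amat <- neurocausal:::mg_add_undirected(amat, 3, 2)
  out <- meek_orient(amat)
  expect_true(neurocausal:::mg_is_directed(out, 3, 2))
  # undirected triangle: no rule fires
  tri <- neurocausal:::mg_new(c("A", "B", "C"))
  tri <- neurocausal:::mg_add_undirected(tri, 1, 2)
  tri <- neurocausal:::mg_add_undirected(tri, 2, 3)
  tri <- neurocausal:::mg_add_undirected(tri, 1, 3)
  expect_identical(meek_orient(tri), tri)
  # idempotence
  expect_identical(meek_orient(out), out)
})

# FGES ------------------------------------------------------------------

test_that("FGES returns the empty graph on independent variables", {
  set.seed(14)
  d <- cbind(A = rnorm(1000), B = rnorm(1000))
  cp <- fges(d)
  expect_identical(neurocausal:::mg_edge_count(cp$amat), 0)
})

test_that("FGES identifies the collider and the chain equivalence class", {
  cp <- fges(bench5000()$collider$data)
  expect_true(neurocausal:::mg_is_directed(cp$amat, 1, 3)) # X --> Z
  expect_true(neurocausal:::mg_is_directed(cp$amat, 2, 3)) # Y --> Z
  expect_false(neurocausal:::mg_has_edge(cp$amat, 1, 2))
  cpc <- fges(bench5000()$chain_forward$data)
  expect_true(neurocausal:::mg_is_undirected(cpc$amat, 1, 3))
  expect_true(neurocausal:::mg_is_undirected(cpc$amat, 2, 3))
  expect_false(neurocausal:::mg_has_edge(cpc$amat, 1, 2))
})

test_that("FGES equals the exhaustive BIC-optimal equivalence class", {
  for (nm in c("collider", "common_cause", "chain_forward",
               "chain_backward")) {
    d <- bench5000()[[nm]]$data
    expect_amat_equal(fges(d), exhaustive_best_cpdag(d))
  }
})

test_that("FGES is deterministic", {
  d <- bench5000()$fig1_like$data[, 1:10]
  expect_identical(fges(d)$amat, fges(d)$amat)
})

# GFCI ------------------------------------------------------------------

test_that("GFCI flags the hidden confounder with a bidirected edge", {
  g <- gfci(bench5000()$hidden_confounder$data)
  nodes <- g$nodes
  xi <- match("X", nodes); yi <- match("Y", nodes)
  expect_identical(g$amat[xi, yi], neurocausal:::MARK_ARROW)
  expect_identical(g$amat[yi, xi], neurocausal:::MARK_ARROW)
  # anchors point into the confounded pair, not a tail-arrow directed edge
  ai <- match("A", nodes)
  expect_identical(g$amat[ai, xi], neurocausal:::MARK_ARROW)
})

test_that("GFCI orients the collider with arrowheads into Z", {
  g <- gfci(bench5000()$collider$data)
  zi <- match("Z", g$nodes)
  expect_identical(g$amat[match("X", g$nodes), zi],
                   neurocausal:::MARK_ARROW)
  expect_identical(g$amat[match("Y", g$nodes), zi],
                   neurocausal:::MARK_ARROW)
  expect_false(neurocausal:::mg_has_edge(g$amat, match("X", g$nodes),
                                         match("Y", g$nodes)))
})

test_that("refinement keeps chain adjacencies and never adds any", {
  d <- bench5000()$chain_forward$data
  cp <- fges(d)
  g <- gfci(d)
  expect_identical(neurocausal:::adjacency_keys(g$amat),
                   neurocausal:::adjacency_keys(cp$amat))
  # adjacency soundness on the larger benchmark
  d31 <- bench5000()$fig1_like$data
  cp31 <- fges(d31)
  g31 <- gfci(d31)
  expect_true(all(neurocausal:::adjacency_keys(g31$amat) %in%
                    neurocausal:::adjacency_keys(cp31$amat)))
  # determinism of the full PAG
  expect_identical(gfci(d)$amat, g$amat)
})

# PAG serialization ------------------------------------------------------

test_that("PAG text format round-trips and parses marks correctly", {
  g <- gfci(bench5000()$hidden_confounder$data)
  path <- withr::local_tempfile(fileext = ".txt")
  write_pag(g, path)
  g2 <- read_pag(path)
  expect_identical(g2$amat, g$amat)
  # empty graph: header only
  empty <- structure(list(nodes = c("A", "B"),
                          amat = neurocausal:::mg_new(c("A", "B"))),
                     class = "pag")
  write_pag(empty, path)
  expect_identical(length(readLines(path)), 1L)
  expect_identical(read_pag(path)$nodes, c("A", "B"))
  # explicit mark semantics of "A o-> B"
  writeLines(c("nodes: A B", "A o-> B"), path)
  g3 <- read_pag(path)
  expect_identical(g3$amat["B", "A"], neurocausal:::MARK_CIRCLE) # at A
  expect_identical(g3$amat["A", "B"], neurocausal:::MARK_ARROW)  # at B
  # unknown token errors with the line number
  writeLines(c("nodes: A B", "A =-> B"), path)
  expect_error(read_pag(path), "line 2",
               class = "neurocausal_parse_error")
})
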