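#' Ground-truth causal graph for simulation
#'
#' A linear-Gaussian structural causal model: a DAG over observed and
#' (optionally) latent nodes, standardized path weights on the directed
#' edges, and per-node Gaussian noise variances. Latent nodes act as
#' unmeasured confounders: they may have children but no observed parents,
#' and their columns are dropped from simulated data.
#'
#' @param nodes character vector of variable names (observed and latent).
#' @param edges data frame with columns `from`, `to`, `weight`.
#' @param latent character vector, subset of `nodes`, flagged hidden.
#' @param noise_var named numeric vector of noise variances (default 1 for
#'   every node).
#' @return an object of class `ground_truth_graph`.
#' @export
ground_truth_graph <- function(nodes, edges = NULL, latent = character(),
                               noise_var = NULL) {
  stopifnot(is.character(nodes), !anyDuplicated(nodes))
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        weight = numeric())
  }
  edges <- as.data.frame(edges)
  stopifnot(all(c("from", "to", "weight") %in% names(edges)))
  nc_validate(all(c(edges$from, edges$to) %in% nodes),
              "edge endpoints must be declared nodes")
  nc_validate(all(latent %in% nodes), "latent nodes must be declared nodes")
  if (is.null(noise_var)) noise_var <- stats::setNames(rep(1, length(nodes)), nodes)
  noise_var <- noise_var[nodes]
  nc_validate(!anyNA(noise_var) && all(noise_var > 0),
              "noise variances must be positive for every node")
  # confounder role: a latent may not have observed parents
  bad <- edges$to %in% latent & !(edges$from %in% latent)
  nc_validate(!any(bad), "latent nodes may not have observed parents")
  g <- structure(list(nodes = nodes, edges = edges, latent = latent,
                      noise_var = noise_var),
                 class = "ground_truth_graph")
  topological_order(g) # errors on cycles
  g
}

# Kahn's algorithm; structural error on a cycle.
topological_order <- function(graph) {
  nodes <- graph$nodes
  indeg <- stats::setNames(integer(length(nodes)), nodes)
  tb <- table(factor(graph$edges$to, levels = nodes))
  indeg[names(tb)] <- as.integer(tb)
  order <- character(0)
  avail <- sort(names(indeg)[indeg == 0L])
  edges <- graph$edges
  while (length(avail)) {
    v <- avail[1]
    avail <- avail[-1]
    order <- c(order, v)
    ch <- edges$to[edges$from == v]
    for (w in ch) {
      indeg[w] <- indeg[w] - 1L
      if (indeg[w] == 0L) avail <- sort(c(avail, w))
    }
  }
  if (length(order) != length(nodes)) {
    nc_stop("cycle detected in ground-truth graph",
            class = "neurocausal_structural_error")
  }
  order
}

#' Implied covariance of a linear-Gaussian SCM
#'
#' Closed form \eqn{(I - B)^{-T} \Psi (I - B)^{-1}} over all nodes, where
#' `B[i, j]` holds the weight of edge i -> j and \eqn{\Psi} the diagonal
#' noise variances. Used by tests as the moment oracle.
#'
#' @param graph a [ground_truth_graph()].
#' @param observed_only drop latent rows/columns (default TRUE).
#' @return covariance matrix.
#' @export
implied_covariance <- function(graph, observed_only = TRUE) {
  nodes <- graph$nodes
  p <- length(nodes)
  B <- matrix(0, p, p, dimnames = list(nodes, nodes))
  if (nrow(graph$edges)) {
    B[cbind(match(graph$edges$from, nodes), match(graph$edges$to, nodes))] <-
      graph$edges$weight
  }
  A <- solve(diag(p) - B) # (I - B)^{-1}; rows = noise source, cols = node
  S <- t(A) %*% diag(graph$noise_var, p) %*% A
  dimnames(S) <- list(nodes, nodes)
  if (observed_only) {
    obs <- setdiff(nodes, graph$latent)
    S <- S[obs, obs, drop = FALSE]
  }
  S
}

#' Simulate data from a linear-Gaussian structural causal model
#'
#' Each node is generated in topological order as the weighted sum of its
#' parents plus independent Gaussian noise. Columns of latent nodes are
#' dropped from the returned matrix.
#'
#' @param graph a [ground_truth_graph()].
#' @param n number of subjects (rows), at least 2.
#' @param seed integer seed; output is deterministic given the seed.
#' @return numeric matrix, n x (number of observed nodes).
#' @export
simulate_linear_sem <- function(graph, n, seed) {
  nc_validate(n >= 2, "n must be at least 2")
  ord <- topological_order(graph)
  nodes <- graph$nodes
  set.seed(seed)
  X <- matrix(0, n, length(nodes), dimnames = list(NULL, nodes))
  edges <- graph$edges
  for (v in ord) {
    eps <- stats::rnorm(n, sd = sqrt(graph$noise_var[[v]]))
    pa <- edges[edges$to == v, , drop = FALSE]
    if (nrow(pa)) {
      X[, v] <- X[, pa$from, drop = FALSE] %*% pa$weight + eps
    } else {
      X[, v] <- eps
    }
  }
  obs <- setdiff(nodes, graph$latent)
  X[, obs, drop = FALSE]
}
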