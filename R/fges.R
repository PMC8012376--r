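#' Configuration for causal discovery
#'
#' @param alpha conditional-independence test level (default 0.01).
#' @param penalty_discount multiplier on the BIC complexity penalty
#'   (default 2).
#' @param max_degree maximum node degree during search (default 100).
#' @param ci_depth maximum conditioning-set size in the refinement phase;
#'   -1 means unlimited.
#' @return list of class `discovery_config`.
#' @export
discovery_config <- function(alpha = 0.01, penalty_discount = 2,
                             max_degree = 100, ci_depth = -1) {
  nc_validate(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  nc_validate(penalty_discount > 0, "penalty_discount must be positive")
  nc_validate(max_degree >= 1, "max_degree must be at least 1")
  structure(list(alpha = alpha, penalty_discount = penalty_discount,
                 max_degree = max_degree, ci_depth = ci_depth),
            class = "discovery_config")
}

# combn that never treats a length-1 vector as seq_len(n)
safe_combn <- function(v, k) {
  if (length(v) < k) return(list())
  if (length(v) == 1L) return(list(v))
  utils::combn(v, k, simplify = FALSE)
}

# subsets of a (sorted) integer vector: by size, then lexicographic; the
# fixed enumeration order is part of the determinism contract
subsets_of <- function(v, max_size = length(v)) {
  out <- list(integer(0))
  if (length(v) == 0 || max_size < 1) return(out)
  for (k in seq_len(min(max_size, length(v)))) {
    out <- c(out, safe_combn(v, k))
  }
  out
}

#' Fast greedy equivalence search
#'
#' Score-based search over Markov equivalence classes with the Gaussian
#' BIC score: a forward phase greedily applies the best valid Insert
#' operator while any improves the total score, then a backward phase
#' applies best valid Delete operators until no improvement. The graph is
#' recompleted to a CPDAG after every operator. Deterministic given the
#' data: ties are broken by lexicographic node order, then operator
#' enumeration order.
#'
#' @param data subjects x variables numeric matrix with column names.
#' @param config a [discovery_config()].
#' @return a [cpdag()].
#' @export
fges <- function(data, config = discovery_config()) {
  data <- as.matrix(data)
  nc_validate(ncol(data) >= 2, "need at least 2 variables")
  sc <- score_cache(data, config$penalty_discount)
  nodes <- sc$nodes
  nc_validate(!is.null(nodes), "data must have column names")
  amat <- mg_new(nodes)
  ordv <- order(nodes) # lexicographic enumeration order
  amat <- fges_forward(amat, sc, config, ordv)
  amat <- fges_backward(amat, sc, config, ordv)
  cpdag(amat)
}

# per-sweep adjacency structure, recomputed after each operator
fges_sweep_state <- function(amat) {
  p <- nrow(amat)
  list(
    adj = lapply(seq_len(p), function(v) which(amat[v, ] != 0L)),
    und = lapply(seq_len(p), function(v)
      which(amat[v, ] == MARK_TAIL & amat[, v] == MARK_TAIL)),
    pa = lapply(seq_len(p), function(v)
      which(amat[, v] == MARK_ARROW & amat[v, ] == MARK_TAIL)),
    # successors traversable on a semi-directed path (v -- w or v --> w)
    succ = lapply(seq_len(p), function(v)
      which((amat[v, ] == MARK_ARROW & amat[, v] == MARK_TAIL) |
              (amat[v, ] == MARK_TAIL & amat[, v] == MARK_TAIL)))
  )
}

# semi-directed reachability using precomputed successor lists
semi_directed_reachable <- function(succ, from, to, blocked, p) {
  visited <- rep(FALSE, p)
  visited[blocked] <- TRUE
  if (visited[from]) return(FALSE)
  visited[from] <- TRUE
  queue <- from
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in succ[[v]]) {
      if (w == to) return(TRUE)
      if (!visited[w]) {
        visited[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  FALSE
}

fges_forward <- function(amat, sc, config, ordv) {
  repeat {
    st <- fges_sweep_state(amat)
    deg <- lengths(st$adj)
    best <- NULL
    best_delta <- 1e-10
    for (x in ordv) {
      for (y in ordv) {
        if (x == y || amat[x, y] != 0L) next
        if (deg[y] >= config$max_degree || deg[x] >= config$max_degree) next
        ney <- st$und[[y]]
        in_adjx <- match(ney, st$adj[[x]], 0L) > 0L
        na_yx <- ney[in_adjx]   # ascending by construction
        t_pool <- ney[!in_adjx]
        pa_y <- st$pa[[y]]
        for (Tset in subsets_of(t_pool)) {
          C <- c(na_yx, Tset)
          base <- c(pa_y, C)
          delta <- local_score_idx(sc, y, c(base, x)) -
            local_score_idx(sc, y, base)
          if (delta > best_delta && mg_is_clique(amat, C) &&
              !semi_directed_reachable(st$succ, y, x, C, nrow(amat))) {
            best_delta <- delta
            best <- list(x = x, y = y, Tset = Tset)
          }
        }
      }
    }
    if (is.null(best)) break
    amat <- mg_add_directed(amat, best$x, best$y)
    for (t in best$Tset) amat <- mg_add_directed(amat, t, best$y)
    amat <- rebuild_cpdag(amat)
  }
  amat
}

fges_backward <- function(amat, sc, config, ordv) {
  repeat {
    st <- fges_sweep_state(amat)
    best <- NULL
    best_delta <- 1e-10
    for (x in ordv) {
      for (y in ordv) {
        if (x == y) next
        # Delete applies to x --> y or x -- y
        directed <- amat[x, y] == MARK_ARROW && amat[y, x] == MARK_TAIL
        undirected <- amat[x, y] == MARK_TAIL && amat[y, x] == MARK_TAIL
        if (!directed && !undirected) next
        ney <- st$und[[y]]
        na_yx <- ney[match(ney, st$adj[[x]], 0L) > 0L]
        pa_y <- st$pa[[y]]
        for (H in subsets_of(na_yx)) {
          keep <- setdiff(na_yx, H)
          if (!mg_is_clique(amat, keep)) next
          base <- setdiff(c(pa_y, keep), x)
          delta <- local_score_idx(sc, y, base) -
            local_score_idx(sc, y, c(base, x))
          if (delta > best_delta) {
            best_delta <- delta
            best <- list(x = x, y = y, H = H)
          }
        }
      }
    }
    if (is.null(best)) break
    amat <- mg_remove_edge(amat, best$x, best$y)
    for (h in best$H) {
      amat <- mg_add_directed(amat, best$y, h)
      if (mg_is_undirected(amat, best$x, h)) {
        amat <- mg_add_directed(amat, best$x, h)
      }
    }
    amat <- rebuild_cpdag(amat)
  }
  amat
}

#' Exhaustive-search BIC-optimal CPDAG (oracle)
#'
#' Enumerates every DAG over the variables of `data` (feasible up to ~5
#' nodes), scores each with the decomposable Gaussian BIC, and returns the
#' CPDAG of the best-scoring DAG. Used as an independent oracle for
#' [fges()] in tests.
#'
#' @inheritParams fges
#' @return a [cpdag()].
#' @export
exhaustive_best_cpdag <- function(data, config = discovery_config()) {
  data <- as.matrix(data)
  p <- ncol(data)
  nc_validate(p <= 5, "exhaustive enumeration is limited to 5 variables")
  sc <- score_cache(data, config$penalty_discount)
  nodes <- sc$nodes
  pairs <- utils::combn(p, 2)
  n_pairs <- ncol(pairs)
  best_score <- -Inf
  best_amat <- NULL
  # each unordered pair is absent (0), forward (1) or backward (2)
  states <- rep(0L, n_pairs)
  repeat {
    amat <- mg_new(nodes)
    for (e in seq_len(n_pairs)) {
      if (states[e] == 1L) amat <- mg_add_directed(amat, pairs[1, e], pairs[2, e])
      if (states[e] == 2L) amat <- mg_add_directed(amat, pairs[2, e], pairs[1, e])
    }
    if (is_acyclic(amat)) {
      s <- sum(vapply(seq_len(p), function(v) {
        local_score_idx(sc, v, sort(mg_parents(amat, v)))
      }, numeric(1)))
      if (s > best_score + 1e-9) {
        best_score <- s
        best_amat <- amat
      }
    }
    # increment base-3 counter
    e <- 1L
    while (e <= n_pairs) {
      states[e] <- states[e] + 1L
      if (states[e] <= 2L) break
      states[e] <- 0L
      e <- e + 1L
    }
    if (e > n_pairs) break
  }
  cpdag(dag_to_cpdag(best_amat))
}

is_acyclic <- function(amat) {
  p <- nrow(amat)
  indeg <- vapply(seq_len(p), function(v) length(mg_parents(amat, v)),
                  integer(1))
  alive <- rep(TRUE, p)
  for (i in seq_len(p)) {
    z <- which(alive & indeg == 0L)
    if (!length(z)) return(FALSE)
    v <- z[1]
    alive[v] <- FALSE
    ch <- mg_children(amat, v)
    indeg[ch] <- indeg[ch] - 1L
  }
  TRUE
}
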