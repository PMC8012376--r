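# GFCI: score-based adjacency search (FGES) followed by
# conditional-independence refinement and FCI orientation, producing a
# partial ancestral graph (PAG) whose endpoint marks (tail, arrow, circle)
# can expose latent confounding as bidirected edges.

pair_key <- function(nodes, a, b) paste(sort(c(nodes[a], nodes[b])),
                                        collapse = "|")

#' Greedy fast causal inference
#'
#' Pipeline: (1) [fges()] supplies candidate adjacencies; (2) each
#' adjacent pair is retested for conditional independence given subsets of
#' the endpoints' adjacency sets and, after provisional collider
#' orientation, of the possible-d-sep sets, removing edges and recording
#' separating sets; (3) all endpoints are reset to circles and unshielded
#' colliders X *-> Z <-* Y are oriented where Z is outside sepset(X, Y);
#' (4) the FCI final orientation rules are applied to fixpoint. Under the
#' assumption of no selection bias the selection-bias rules (R5-R7) never
#' fire and are omitted.
#'
#' @param data subjects x variables numeric matrix with column names.
#' @param config a [discovery_config()].
#' @return object of class `pag` with fields `nodes`, `amat` (endpoint-mark
#'   matrix), `sepsets`, and `removed` (edges pruned in the CI phase).
#' @export
gfci <- function(data, config = discovery_config()) {
  data <- as.matrix(data)
  cp <- fges(data, config)
  st <- ci_suffstat(data)
  nodes <- cp$nodes
  skel <- cp$amat
  sep <- new.env(parent = emptyenv())
  removed <- list()

  # --- stage 1: prune with subsets of adjacency sets -----------------
  max_d <- if (config$ci_depth >= 0) config$ci_depth else nrow(skel) - 2
  d <- 0L
  repeat {
    changed <- FALSE
    pairs <- mg_edge_pairs(skel)
    if (nrow(pairs)) {
      for (r in seq_len(nrow(pairs))) {
        x <- pairs[r, 1]; y <- pairs[r, 2]
        if (!mg_has_edge(skel, x, y)) next
        res <- test_pair_at_depth(st, skel, x, y, d, config$alpha)
        if (!is.null(res)) {
          skel <- mg_remove_edge(skel, x, y)
          sep[[pair_key(nodes, x, y)]] <- nodes[res]
          removed <- c(removed, list(data.frame(
            from = nodes[min(x, y)], to = nodes[max(x, y)],
            phase = "ci_adjacency")))
          changed <- TRUE
        }
      }
    }
    d <- d + 1L
    max_adj <- max(c(0L, vapply(seq_along(nodes), function(v)
      length(mg_adjacent(skel, v)), integer(1))))
    if (d > max_d || d > max_adj - 1L) break
  }

  # --- provisional orientation, then possible-d-sep pruning ----------
  amat <- orient_colliders(skel, cp$amat, st, sep, config)
  pairs <- mg_edge_pairs(amat)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      x <- pairs[r, 1]; y <- pairs[r, 2]
      if (!mg_has_edge(amat, x, y)) next
      res <- test_pair_pdsep(st, amat, x, y, config)
      if (!is.null(res)) {
        amat <- mg_remove_edge(amat, x, y)
        sep[[pair_key(nodes, x, y)]] <- nodes[res]
        removed <- c(removed, list(data.frame(
          from = nodes[min(x, y)], to = nodes[max(x, y)],
          phase = "ci_pdsep")))
      }
    }
  }

  # --- final orientation ---------------------------------------------
  amat <- orient_colliders(amat, cp$amat, st, sep, config)
  amat <- fci_orient_rules(amat, sep)

  sepsets <- as.list(sep)
  structure(list(nodes = nodes, amat = amat, sepsets = sepsets,
                 removed = if (length(removed)) do.call(rbind, removed)
                           else data.frame(from = character(),
                                           to = character(),
                                           phase = character()),
                 fges_cpdag = cp, config = config),
            class = "pag")
}

# test x _||_ y | S over all size-d subsets of either endpoint's adjacency
# set; returns the first separating set found (enumeration order fixed)
test_pair_at_depth <- function(st, skel, x, y, d, alpha) {
  seen <- character(0)
  for (side in list(c(x, y), c(y, x))) {
    adj <- sort(setdiff(mg_adjacent(skel, side[1]), side[2]))
    if (length(adj) < d) next
    for (S in if (d == 0L) list(integer(0)) else safe_combn(adj, d)) {
      key <- paste(S, collapse = ",")
      if (key %in% seen) next
      seen <- c(seen, key)
      res <- fisher_z_ci_test(st, st$nodes[x], st$nodes[y],
                              st$nodes[S], alpha)
      if (res$independent) return(S)
    }
  }
  NULL
}

# Possible-D-Sep(x): nodes reachable by a path on which every interior
# vertex is either a collider or the middle of a triangle.
possible_d_sep <- function(amat, x) {
  p <- nrow(amat)
  reached <- matrix(FALSE, p, p) # state (prev, cur)
  queue <- lapply(mg_adjacent(amat, x), function(v) c(x, v))
  out <- logical(p)
  for (q in queue) {
    reached[q[1], q[2]] <- TRUE
    out[q[2]] <- TRUE
  }
  while (length(queue)) {
    state <- queue[[1]]
    queue <- queue[-1]
    a <- state[1]; b <- state[2]
    for (cc in mg_adjacent(amat, b)) {
      if (cc == a) next
      collider <- amat[a, b] == MARK_ARROW && amat[cc, b] == MARK_ARROW
      triangle <- mg_has_edge(amat, a, cc)
      if ((collider || triangle) && !reached[b, cc]) {
        reached[b, cc] <- TRUE
        out[cc] <- TRUE
        queue <- c(queue, list(c(b, cc)))
      }
    }
  }
  out[x] <- FALSE
  which(out)
}

test_pair_pdsep <- function(st, amat, x, y, config) {
  for (side in list(c(x, y), c(y, x))) {
    pds <- sort(setdiff(possible_d_sep(amat, side[1]), c(x, y)))
    # subsets of the endpoint's adjacency set were already tested
    max_d <- if (config$ci_depth >= 0) min(config$ci_depth, length(pds))
             else length(pds)
    if (max_d < 1) next
    for (d in seq_len(max_d)) {
      if (length(pds) < d) break
      for (S in safe_combn(pds, d)) {
        res <- fisher_z_ci_test(st, st$nodes[x], st$nodes[y],
                                st$nodes[S], config$alpha)
        if (res$independent) return(S)
      }
    }
  }
  NULL
}

# Reset all endpoint marks to circles, then orient unshielded colliders
# X *-> Z <-* Y where Z is not in sepset(X, Y). Pairs non-adjacent since
# the FGES stage have no recorded sepset; one is searched for in the
# current skeleton, falling back to the FGES collider orientation when no
# separating set is found.
orient_colliders <- function(skel, fges_amat, st, sep, config) {
  nodes <- mg_nodes(skel)
  amat <- skel
  amat[amat != 0L] <- MARK_CIRCLE
  p <- nrow(amat)
  for (z in seq_len(p)) {
    adj <- mg_adjacent(amat, z)
    if (length(adj) < 2) next
    for (i in seq_along(adj)) {
      for (j in seq_along(adj)) {
        if (i >= j) next
        x <- adj[i]; y <- adj[j]
        if (mg_has_edge(amat, x, y)) next
        key <- pair_key(nodes, x, y)
        S <- sep[[key]]
        if (is.null(S)) {
          S <- find_sepset(st, amat, x, y, config)
          if (!is.null(S)) {
            sep[[key]] <- nodes[S]
            S <- nodes[S]
          }
        }
        collider <- if (!is.null(S)) {
          !(nodes[z] %in% S)
        } else {
          # fall back to the score-phase orientation
          fges_amat[x, z] == MARK_ARROW && fges_amat[y, z] == MARK_ARROW
        }
        if (collider) {
          amat[x, z] <- MARK_ARROW
          amat[y, z] <- MARK_ARROW
        }
      }
    }
  }
  amat
}

find_sepset <- function(st, skel, x, y, config) {
  max_d <- if (config$ci_depth >= 0) config$ci_depth else nrow(skel) - 2
  for (d in 0:max_d) {
    res <- test_pair_at_depth(st, skel, x, y, d, config$alpha)
    if (!is.null(res)) return(res)
    max_adj <- max(length(mg_adjacent(skel, x)), length(mg_adjacent(skel, y)))
    if (d >= max_adj - 1L) break
  }
  NULL
}
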