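# Mixed-graph machinery shared by FGES (CPDAGs) and GFCI (PAGs).
#
# A graph over p named nodes is stored as a p x p endpoint-mark matrix:
# amat[a, b] is the mark at the *b* end of the edge between a and b,
# 0 = no edge, 1 = tail, 2 = arrow, 3 = circle. So a directed edge
# a --> b has amat[a, b] = 2 and amat[b, a] = 1; an undirected CPDAG edge
# has tails at both ends; a bidirected (confounded) PAG edge has arrows at
# both ends.

MARK_NONE <- 0L
MARK_TAIL <- 1L
MARK_ARROW <- 2L
MARK_CIRCLE <- 3L

mg_new <- function(nodes) {
  p <- length(nodes)
  matrix(0L, p, p, dimnames = list(nodes, nodes))
}

mg_nodes <- function(amat) rownames(amat)

mg_adjacent <- function(amat, a) which(amat[a, ] != 0L)

mg_has_edge <- function(amat, a, b) amat[a, b] != 0L

mg_remove_edge <- function(amat, a, b) {
  amat[a, b] <- 0L
  amat[b, a] <- 0L
  amat
}

mg_add_directed <- function(amat, a, b) {
  amat[a, b] <- MARK_ARROW
  amat[b, a] <- MARK_TAIL
  amat
}

mg_add_undirected <- function(amat, a, b) {
  amat[a, b] <- MARK_TAIL
  amat[b, a] <- MARK_TAIL
  amat
}

mg_is_directed <- function(amat, a, b) {
  amat[a, b] == MARK_ARROW & amat[b, a] == MARK_TAIL
}

mg_is_undirected <- function(amat, a, b) {
  amat[a, b] == MARK_TAIL & amat[b, a] == MARK_TAIL
}

mg_parents <- function(amat, b) {
  which(amat[, b] == MARK_ARROW & amat[b, ] == MARK_TAIL)
}

mg_children <- function(amat, a) {
  which(amat[a, ] == MARK_ARROW & amat[, a] == MARK_TAIL)
}

mg_neighbors_und <- function(amat, a) {
  which(amat[a, ] == MARK_TAIL & amat[, a] == MARK_TAIL)
}

mg_edge_count <- function(amat) sum(amat != 0L) / 2

# all unordered adjacent pairs, lexicographic by node name
mg_edge_pairs <- function(amat) {
  idx <- which(amat != 0L & upper.tri(amat), arr.ind = TRUE)
  if (!nrow(idx)) return(idx)
  idx[order(rownames(amat)[idx[, 1]], rownames(amat)[idx[, 2]]), ,
      drop = FALSE]
}

# is every pair in `set` adjacent (a clique in the skeleton)?
mg_is_clique <- function(amat, set) {
  if (length(set) < 2) return(TRUE)
  sub <- amat[set, set, drop = FALSE]
  all(sub[upper.tri(sub)] != 0L)
}

# Does a semi-directed path (edges undirected or pointing away from `from`)
# exist from `from` to `to` avoiding `blocked`? Used by the FGES Insert
# validity condition.
mg_semi_directed_path_exists <- function(amat, from, to, blocked) {
  p <- nrow(amat)
  visited <- rep(FALSE, p)
  visited[blocked] <- TRUE
  queue <- from
  if (visited[from]) return(FALSE)
  visited[from] <- TRUE
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    # traversable: v -- w or v --> w  (never against an arrow into v)
    nxt <- which((amat[v, ] == MARK_ARROW & amat[, v] == MARK_TAIL) |
                   (amat[v, ] == MARK_TAIL & amat[, v] == MARK_TAIL))
    for (w in nxt) {
      if (w == to) return(TRUE)
      if (!visited[w]) {
        visited[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  FALSE
}

# directed path (all edges a --> b) existence
mg_directed_path_exists <- function(amat, from, to) {
  p <- nrow(amat)
  visited <- rep(FALSE, p)
  queue <- from
  visited[from] <- TRUE
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    for (w in mg_children(amat, v)) {
      if (w == to) return(TRUE)
      if (!visited[w]) {
        visited[w] <- TRUE
        queue <- c(queue, w)
      }
    }
  }
  FALSE
}

#' Apply Meek's orientation rules to a partially directed graph
#'
#' Closes a pattern (mix of directed and undirected edges) under Meek's
#' rules R1-R4, orienting every undirected edge whose direction is forced
#' by the requirement that no new unshielded collider and no directed
#' cycle be created.
#'
#' @param graph a `cpdag` object or a bare endpoint-mark matrix.
#' @return same type as the input, with forced orientations applied.
#' @export
meek_orient <- function(graph) {
  amat <- if (inherits(graph, "cpdag")) graph$amat else graph
  amat <- meek_closure(amat)
  if (inherits(graph, "cpdag")) cpdag(amat) else amat
}

meek_closure <- function(amat) {
  p <- nrow(amat)
  repeat {
    changed <- FALSE
    und <- which(amat == MARK_TAIL & t(amat) == MARK_TAIL & upper.tri(amat),
                 arr.ind = TRUE)
    if (!nrow(und)) break
    for (r in seq_len(nrow(und))) {
      for (swap in 1:2) {
        b <- if (swap == 1) und[r, 1] else und[r, 2]
        cc <- if (swap == 1) und[r, 2] else und[r, 1]
        if (!mg_is_undirected(amat, b, cc)) next
        if (meek_forces(amat, b, cc)) {
          amat <- mg_add_directed(amat, b, cc)
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  amat
}

# should b -- c be oriented b --> c by one of R1-R4?
meek_forces <- function(amat, b, cc) {
  # R1: a --> b, b -- c, a and c nonadjacent  =>  b --> c
  for (a in mg_parents(amat, b)) {
    if (a != cc && !mg_has_edge(amat, a, cc)) return(TRUE)
  }
  # R2: b --> d --> c with b -- c  =>  b --> c
  for (d in mg_children(amat, b)) {
    if (mg_is_directed(amat, d, cc)) return(TRUE)
  }
  # R3: b -- d1 --> ? ... pattern: b -- c with b -- d, b -- e, d --> c,
  # e --> c, d and e nonadjacent  =>  b --> c
  pa_c <- mg_parents(amat, cc)
  cand <- intersect(mg_neighbors_und(amat, b), pa_c)
  if (length(cand) >= 2) {
    for (i in seq_along(cand)) {
      for (j in seq_along(cand)) {
        if (i < j && !mg_has_edge(amat, cand[i], cand[j])) return(TRUE)
      }
    }
  }
  # R4: b -- c with b -- d, d --> e, e --> c, d and c nonadjacent  =>  b --> c
  for (d in mg_neighbors_und(amat, b)) {
    if (d == cc || mg_has_edge(amat, d, cc)) next
    for (e in mg_children(amat, d)) {
      if (mg_is_directed(amat, e, cc)) return(TRUE)
    }
  }
  FALSE
}

# Dor-Tarsi: orient a PDAG into a consistent DAG extension. Errors if none
# exists (should not happen for PDAGs arising from valid FGES operators).
pdag_to_dag <- function(amat) {
  res <- amat
  work <- amat
  alive <- rep(TRUE, nrow(amat))
  while (any(alive)) {
    found <- FALSE
    for (x in which(alive)) {
      if (length(mg_children(work, x))) next # must be a sink
      nb_und <- mg_neighbors_und(work, x)
      adj_x <- mg_adjacent(work, x)
      ok <- all(vapply(nb_und, function(y) {
        others <- setdiff(adj_x, y)
        all(work[y, others] != 0L | y == others)
      }, logical(1)))
      if (!ok) next
      for (y in nb_und) res <- mg_add_directed(res, y, x)
      # remove x
      work[x, ] <- 0L
      work[, x] <- 0L
      alive[x] <- FALSE
      found <- TRUE
      break
    }
    if (!found) nc_stop("PDAG admits no consistent DAG extension",
                        class = "neurocausal_internal_error")
  }
  res
}

# CPDAG of a DAG: skeleton plus v-structures, closed under Meek's rules.
dag_to_cpdag <- function(amat) {
  p <- nrow(amat)
  out <- mg_new(mg_nodes(amat))
  idx <- which(amat == MARK_ARROW, arr.ind = TRUE)
  for (r in seq_len(nrow(idx))) {
    out <- mg_add_undirected(out, idx[r, 1], idx[r, 2])
  }
  # v-structures: a --> b <-- c with a, c nonadjacent
  for (b in seq_len(p)) {
    pa <- mg_parents(amat, b)
    if (length(pa) < 2) next
    for (i in seq_along(pa)) {
      for (j in seq_along(pa)) {
        if (i < j && !mg_has_edge(amat, pa[i], pa[j])) {
          out <- mg_add_directed(out, pa[i], b)
          out <- mg_add_directed(out, pa[j], b)
        }
      }
    }
  }
  meek_closure(out)
}

# Rebuild the completed CPDAG after an FGES operator application: extend
# the post-operator PDAG to a DAG, then recompute its equivalence class.
rebuild_cpdag <- function(amat) {
  dag_to_cpdag(pdag_to_dag(amat))
}

#' Completed partially directed acyclic graph
#'
#' Thin S3 wrapper around an endpoint-mark matrix representing a Markov
#' equivalence class of DAGs (directed plus undirected edges).
#'
#' @param amat endpoint-mark matrix (see package internals).
#' @export
cpdag <- function(amat) {
  structure(list(nodes = mg_nodes(amat), amat = amat), class = "cpdag")
}

#' @export
print.cpdag <- function(x, ...) {
  cat("CPDAG with", length(x$nodes), "nodes and",
      mg_edge_count(x$amat), "edges\n")
  cat(format_edge_lines(x$amat), sep = "\n")
  invisible(x)
}

#' Edges of a graph object as a data frame
#'
#' @param graph a `cpdag` or `pag`.
#' @return data frame with `from`, `to`, `edge` (display string), and the
#'   endpoint marks `mark_from`, `mark_to`.
#' @export
graph_edges <- function(graph) {
  amat <- graph$amat
  idx <- mg_edge_pairs(amat)
  nodes <- mg_nodes(amat)
  if (!nrow(idx)) {
    return(data.frame(from = character(), to = character(),
                      edge = character(), mark_from = character(),
                      mark_to = character()))
  }
  mark_name <- c("tail", "arrow", "circle")
  data.frame(
    from = nodes[idx[, 1]], to = nodes[idx[, 2]],
    edge = vapply(seq_len(nrow(idx)), function(r) {
      edge_string(amat, idx[r, 1], idx[r, 2])
    }, character(1)),
    mark_from = mark_name[amat[cbind(idx[, 2], idx[, 1])]],
    mark_to = mark_name[amat[cbind(idx[, 1], idx[, 2])]]
  )
}

# display string "A o-> B" for the edge between node indices a < b
edge_string <- function(amat, a, b) {
  nodes <- mg_nodes(amat)
  left <- c("-", "<", "o")[amat[b, a]]  # mark at a
  right <- c("-", ">", "o")[amat[a, b]] # mark at b
  paste0(nodes[a], " ", left, "-", right, " ", nodes[b])
}

format_edge_lines <- function(amat) {
  idx <- mg_edge_pairs(amat)
  if (!nrow(idx)) return(character(0))
  vapply(seq_len(nrow(idx)), function(r) {
    edge_string(amat, idx[r, 1], idx[r, 2])
  }, character(1))
}

# unordered adjacency pairs as a sorted "a|b" character key
adjacency_keys <- function(amat) {
  idx <- mg_edge_pairs(amat)
  nodes <- mg_nodes(amat)
  if (!nrow(idx)) return(character(0))
  keys <- vapply(seq_len(nrow(idx)), function(r) {
    paste(sort(c(nodes[idx[r, 1]], nodes[idx[r, 2]])), collapse = "|")
  }, character(1))
  sort(keys)
}
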