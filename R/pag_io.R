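#' @export
print.pag <- function(x, ...) {
  cat("PAG with", length(x$nodes), "nodes and", mg_edge_count(x$amat),
      "edges\n")
  cat(format_edge_lines(x$amat), sep = "\n")
  invisible(x)
}

#' Serialize a PAG (or CPDAG) as a text edge list
#'
#' Format: a `nodes:` header line listing all variables, then one edge
#' per line, e.g. `A --> B`, `A <-> B`, `A o-> B`, `A o-o B`, `A --- B`.
#' The endpoint characters encode the marks (`-` tail, `<`/`>` arrow,
#' `o` circle). `read_pag(write_pag(g))` is the identity.
#'
#' @param graph a `pag` or `cpdag`.
#' @param path output file.
#' @export
write_pag <- function(graph, path) {
  amat <- graph$amat
  lines <- c(paste("nodes:", paste(mg_nodes(amat), collapse = " ")),
             format_edge_lines(amat))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_pag
#' @return `read_pag` returns a `pag` object.
#' @export
read_pag <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  nc_validate(length(lines) >= 1 && startsWith(lines[1], "nodes:"),
              "missing 'nodes:' header")
  nodes <- strsplit(trimws(sub("^nodes:", "", lines[1])), "\\s+")[[1]]
  nodes <- nodes[nzchar(nodes)]
  amat <- mg_new(nodes)
  left_marks <- c("-" = MARK_TAIL, "<" = MARK_ARROW, "o" = MARK_CIRCLE)
  right_marks <- c("-" = MARK_TAIL, ">" = MARK_ARROW, "o" = MARK_CIRCLE)
  for (i in seq_along(lines)[-1]) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 3) {
      nc_stop("parse error at line ", i, ": expected 'A <edge> B'",
              class = "neurocausal_parse_error")
    }
    a <- tok[1]; es <- tok[2]; b <- tok[3]
    m <- regmatches(es, regexec("^([<o-])-([>o-])$", es))[[1]]
    if (length(m) != 3 || !(a %in% nodes) || !(b %in% nodes)) {
      nc_stop("parse error at line ", i, ": unknown edge token '",
              es, "' or node", class = "neurocausal_parse_error")
    }
    amat[b, a] <- unname(left_marks[m[2]])  # mark at a
    amat[a, b] <- unname(right_marks[m[3]]) # mark at b
  }
  structure(list(nodes = nodes, amat = amat, sepsets = list(),
                 removed = NULL), class = "pag")
}

#' Write a ground-truth graph as an edge list with a JSON sidecar
#'
#' The edge list uses the same text format as [write_pag()] (directed
#' edges only); a JSON sidecar at `<path>.json` holds the weights, latent
#' flags and noise variances.
#'
#' @param graph a [ground_truth_graph()].
#' @param path output file for the edge list.
#' @export
write_ground_truth_graph <- function(graph, path) {
  lines <- c(paste("nodes:", paste(graph$nodes, collapse = " ")),
             sprintf("%s --> %s", graph$edges$from, graph$edges$to))
  writeLines(lines, path)
  jsonlite::write_json(
    list(edges = graph$edges, latent = graph$latent,
         noise_var = as.list(graph$noise_var)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# endpoint-mark matrix of the true PAG-level adjacency structure over
# observed nodes (adjacency = edge between observed nodes, or common
# latent parent); used to score benchmark recovery
true_observed_adjacencies <- function(graph) {
  obs <- setdiff(graph$nodes, graph$latent)
  amat <- mg_new(obs)
  e <- graph$edges
  for (r in seq_len(nrow(e))) {
    if (e$from[r] %in% obs && e$to[r] %in% obs) {
      amat <- mg_add_undirected(amat, e$from[r], e$to[r])
    }
  }
  for (l in graph$latent) {
    ch <- intersect(e$to[e$from == l], obs)
    if (length(ch) >= 2) {
      for (i in seq_along(ch)) {
        for (j in seq_along(ch)) {
          if (i < j) amat <- mg_add_undirected(amat, ch[i], ch[j])
        }
      }
    }
  }
  amat
}

#' Compare discovered adjacencies with ground truth
#'
#' True adjacencies are edges between observed nodes plus pairs sharing a
#' hidden common cause (which a PAG represents as a bidirected edge).
#'
#' @param graph a [ground_truth_graph()].
#' @param discovered a `pag` or `cpdag` over the observed nodes.
#' @return list with `recall`, `false_discovery_rate`, `n_true`, `n_found`,
#'   `n_correct`.
#' @export
adjacency_recovery <- function(graph, discovered) {
  truth <- adjacency_keys(true_observed_adjacencies(graph))
  found <- adjacency_keys(discovered$amat)
  correct <- intersect(truth, found)
  list(recall = if (length(truth)) length(correct) / length(truth) else NA,
       false_discovery_rate =
         if (length(found)) 1 - length(correct) / length(found) else 0,
       n_true = length(truth), n_found = length(found),
       n_correct = length(correct))
}
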