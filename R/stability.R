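#' Jackknife edge-stability analysis
#'
#' Repeatedly draws `floor(fraction * n)` rows without replacement, reruns
#' [gfci()] on each subsample, and tallies per node pair (a) how often the
#' pair is adjacent and (b) how often it appears with exactly the modal
#' endpoint marks. Per-replicate child seeds are derived from the master
#' seed by replicate index, so the report is reproducible and independent
#' of execution order.
#'
#' @param data subjects x variables numeric matrix.
#' @param config a [discovery_config()].
#' @param fraction subsample proportion in (0, 1] (default 0.9).
#' @param reps number of replicates (default 1000).
#' @param seed master seed.
#' @return object of class `stability_report`.
#' @export
jackknife <- function(data, config = discovery_config(), fraction = 0.9,
                      reps = 1000, seed = 1) {
  data <- as.matrix(data)
  n <- nrow(data)
  nc_validate(fraction > 0 && fraction <= 1, "fraction must be in (0, 1]")
  nc_validate(reps >= 1, "reps must be at least 1")
  m <- floor(fraction * n)
  nc_validate(m >= ncol(data) + 2,
              "subsample of ", m, " rows is too small for ", ncol(data),
              " variables")
  adj_tally <- new.env(parent = emptyenv())
  edge_tally <- new.env(parent = emptyenv())
  for (r in seq_len(reps)) {
    set.seed(child_seed(seed, paste0("jackknife_rep", r)))
    idx <- if (m == n) seq_len(n) else sample.int(n, m)
    g <- gfci(data[idx, , drop = FALSE], config)
    ed <- graph_edges(g)
    for (i in seq_len(nrow(ed))) {
      k <- paste(sort(c(ed$from[i], ed$to[i])), collapse = "|")
      adj_tally[[k]] <- (adj_tally[[k]] %||% 0L) + 1L
      ek <- ed$edge[i]
      tab <- edge_tally[[k]] %||% integer(0)
      tab[ek] <- (if (ek %in% names(tab)) tab[[ek]] else 0L) + 1L
      edge_tally[[k]] <- tab
    }
  }
  pairs <- sort(ls(adj_tally))
  tab <- data.frame(
    node_a = vapply(strsplit(pairs, "\\|"), `[`, character(1), 1),
    node_b = vapply(strsplit(pairs, "\\|"), `[`, character(1), 2),
    adjacency_freq = vapply(pairs, function(k) adj_tally[[k]] / reps,
                            numeric(1)),
    mark_freq = vapply(pairs, function(k) max(edge_tally[[k]]) / reps,
                       numeric(1)),
    modal_edge = vapply(pairs, function(k) {
      tt <- edge_tally[[k]]
      names(tt)[which.max(tt)]
    }, character(1)),
    row.names = NULL)
  structure(list(table = tab, reps = reps, fraction = fraction,
                 seed = seed, nodes = colnames(data)),
            class = "stability_report")
}

#' @export
print.stability_report <- function(x, ...) {
  cat(sprintf("Jackknife stability: %d reps at fraction %.2f\n",
              x$reps, x$fraction))
  print(utils::head(x$table[order(-x$table$adjacency_freq), ], 20),
        digits = 3)
  invisible(x)
}

#' Adjacency and exact-mark frequency of a node pair
#'
#' @param report a [jackknife()] report.
#' @param a,b node names.
#' @return named numeric vector `c(adjacency, mark)`; (0, 0) for pairs
#'   never seen.
#' @export
edge_frequency <- function(report, a, b) {
  nc_validate(all(c(a, b) %in% report$nodes),
              "unknown node: ", paste(setdiff(c(a, b), report$nodes),
                                      collapse = ", "))
  key <- sort(c(a, b))
  row <- report$table[report$table$node_a == key[1] &
                        report$table$node_b == key[2], ]
  if (!nrow(row)) return(c(adjacency = 0, mark = 0))
  c(adjacency = row$adjacency_freq, mark = row$mark_freq)
}

#' Write a stability report as a tab-separated table
#'
#' @param report a [jackknife()] report.
#' @param path output file.
#' @param provenance optional `#` header lines.
#' @export
write_stability_report <- function(report, path, provenance = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(report$table, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
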