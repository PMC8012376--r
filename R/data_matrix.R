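#' Read and write subject-by-variable data matrices
#'
#' The pipeline's common currency is a numeric subjects x variables table
#' with a header row of variable names, stored as comma-separated text.
#' Lines starting with `#` are provenance comments (seed, configuration
#' hash) and are ignored on read.
#'
#' @param path file path.
#' @return `read_data_matrix` returns a numeric matrix with column names.
#' @export
read_data_matrix <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", check.names = FALSE)
  m <- as.matrix(df)
  if (!is.numeric(m)) nc_stop("non-numeric columns in data matrix: ", path,
                              class = "neurocausal_validation_error")
  m
}

#' @rdname read_data_matrix
#' @param x numeric matrix with column names.
#' @param provenance optional character vector written as leading `#` comment
#'   lines (e.g. seed and config hash).
#' @export
write_data_matrix <- function(x, path, provenance = NULL) {
  stopifnot(is.matrix(x), !is.null(colnames(x)))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Read and write a parcel-to-network partition table
#'
#' Tab-separated, two columns: `parcel_id` and `network_label`.
#'
#' @param path file path.
#' @return named character vector mapping parcel id to network label.
#' @export
read_partition <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#", stringsAsFactors = FALSE)
  nc_validate(ncol(df) >= 2, "partition table needs parcel_id and network_label")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' @rdname read_partition
#' @param partition named character vector (names = parcel ids, values =
#'   network labels).
#' @export
write_partition <- function(partition, path) {
  df <- data.frame(parcel_id = names(partition),
                   network_label = unname(partition))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
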