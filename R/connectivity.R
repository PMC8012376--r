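#' Fisher z-transform of a correlation
#'
#' Variance-stabilizing transform `z = atanh(r)`. Defined only for
#' |r| < 1; values at or beyond 1 are a domain error, never clipped.
#'
#' @param r correlation(s) in (-1, 1).
#' @return transformed value(s).
#' @export
fisher_z <- function(r) {
  if (any(abs(r) >= 1)) {
    nc_stop("fisher_z undefined for |r| >= 1",
            class = "neurocausal_domain_error")
  }
  atanh(r)
}

#' Mean within-network Fisher-z connectivity of one run
#'
#' For each network: Pearson correlations between all unordered distinct
#' parcel pairs inside the network, Fisher z-transformed, then averaged.
#'
#' @param timeseries parcels x timepoints matrix; row names are parcel ids.
#' @param partition named character vector parcel_id -> network label
#'   covering every row.
#' @return named numeric vector, one mean z per network label.
#' @export
within_network_connectivity <- function(timeseries, partition) {
  nc_validate(ncol(timeseries) >= 3, "need at least 3 timepoints")
  parcels <- rownames(timeseries)
  nc_validate(!is.null(parcels) && all(parcels %in% names(partition)),
              "partition must cover all parcel rows")
  sds <- apply(timeseries, 1, stats::sd)
  if (any(sds == 0)) {
    nc_stop("constant parcel series: ",
            paste(parcels[sds == 0], collapse = ", "),
            class = "neurocausal_validation_error")
  }
  labels <- partition[parcels]
  networks <- unique(unname(labels))
  out <- stats::setNames(numeric(length(networks)), networks)
  for (nw in networks) {
    idx <- which(labels == nw)
    if (length(idx) < 2) {
      nc_stop("network has fewer than 2 parcels: ", nw,
              class = "neurocausal_validation_error")
    }
    cm <- stats::cor(t(timeseries[idx, , drop = FALSE]))
    rs <- cm[upper.tri(cm)]
    out[[nw]] <- mean(fisher_z(rs))
  }
  out
}

#' Combine per-run connectivity profiles
#'
#' Per-network unweighted mean of the per-run Fisher-z summaries.
#'
#' @param per_run_profiles list of named numeric vectors with identical
#'   network label sets (as from [within_network_connectivity()]).
#' @return named numeric vector with attribute `runs_used`.
#' @export
combine_runs <- function(per_run_profiles) {
  nc_validate(length(per_run_profiles) >= 1, "need at least one run")
  labs <- names(per_run_profiles[[1]])
  for (pr in per_run_profiles) {
    nc_validate(setequal(names(pr), labs), "mismatched network labels across runs")
  }
  m <- do.call(rbind, lapply(per_run_profiles, function(pr) pr[labs]))
  out <- colMeans(m)
  attr(out, "runs_used") <- length(per_run_profiles)
  out
}

#' Connectivity profiles for a set of subjects
#'
#' Applies [within_network_connectivity()] to each subject's run(s) and
#' assembles a subjects x networks matrix. Multiple runs per subject are
#' combined by averaging the per-run Fisher-z summaries (`combine =
#' "mean"`), or by concatenating runs in time before correlating
#' (`combine = "concat"`).
#'
#' @param subject_runs either a list of parcels x timepoints matrices (one
#'   run per subject) or a list of lists of such matrices (several runs per
#'   subject).
#' @param partition named character vector parcel_id -> network label.
#' @param combine `"mean"` (default) or `"concat"`.
#' @return subjects x networks numeric matrix.
#' @export
connectivity_profiles <- function(subject_runs, partition,
                                  combine = c("mean", "concat")) {
  combine <- match.arg(combine)
  rows <- lapply(subject_runs, function(runs) {
    if (is.matrix(runs)) runs <- list(runs)
    if (combine == "concat" && length(runs) > 1) {
      runs <- list(do.call(cbind, runs))
    }
    combine_runs(lapply(runs, within_network_connectivity, partition = partition))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- names(subject_runs)
  out
}
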