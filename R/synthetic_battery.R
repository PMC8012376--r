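#' Specification of a correlated-factor measurement model
#'
#' Describes the generative model behind an item battery: item loadings on
#' k factors, a factor correlation matrix (oblique factors allowed), and
#' per-item uniquenesses. The implied item correlation matrix is
#' \eqn{\Lambda \Phi \Lambda^T + \mathrm{diag}(\psi)}.
#'
#' @param loadings items x factors numeric matrix.
#' @param phi factor correlation matrix (default identity).
#' @param uniquenesses per-item positive values; default `1 - communality`
#'   so items have unit variance.
#' @return object of class `factor_spec`.
#' @export
factor_spec <- function(loadings, phi = NULL, uniquenesses = NULL) {
  loadings <- as.matrix(loadings)
  k <- ncol(loadings)
  if (is.null(phi)) phi <- diag(k)
  phi <- as.matrix(phi)
  nc_validate(nrow(phi) == k && ncol(phi) == k, "phi must be k x k")
  nc_validate(max(abs(phi - t(phi))) < 1e-10, "phi must be symmetric")
  nc_validate(max(abs(diag(phi) - 1)) < 1e-10, "phi must have unit diagonal")
  nc_validate(is_pd(phi), "phi must be positive definite")
  common <- loadings %*% phi %*% t(loadings)
  if (is.null(uniquenesses)) uniquenesses <- 1 - diag(common)
  nc_validate(all(uniquenesses > 0), "uniquenesses must be positive")
  sigma <- common + diag(uniquenesses, nrow(loadings))
  nc_validate(is_pd(sigma), "implied item covariance is not positive definite")
  if (is.null(rownames(loadings)))
    rownames(loadings) <- sprintf("item%02d", seq_len(nrow(loadings)))
  structure(list(loadings = loadings, phi = phi,
                 uniquenesses = stats::setNames(uniquenesses, rownames(loadings)),
                 sigma = sigma),
            class = "factor_spec")
}

#' Block-structure factor specification
#'
#' Convenience constructor: `k` factors, `items_per_factor` items each,
#' every item loading `loading` on its own factor and 0 elsewhere.
#'
#' @param k number of factors.
#' @param items_per_factor items per block.
#' @param loading primary loading (default 0.8).
#' @param phi factor correlation matrix (default identity).
#' @export
block_factor_spec <- function(k, items_per_factor, loading = 0.8, phi = NULL) {
  p <- k * items_per_factor
  L <- matrix(0, p, k)
  for (j in seq_len(k)) {
    L[((j - 1) * items_per_factor + 1):(j * items_per_factor), j] <- loading
  }
  rownames(L) <- sprintf("item%03d", seq_len(p))
  factor_spec(L, phi = phi)
}

#' Simulate an item battery from a correlated-factor model
#'
#' Rows are drawn from a zero-mean Gaussian with covariance
#' \eqn{\Lambda \Phi \Lambda^T + \mathrm{diag}(\psi)}.
#'
#' @param spec a [factor_spec()].
#' @param n number of subjects.
#' @param seed integer seed.
#' @return n x items numeric matrix with item names as columns.
#' @export
simulate_factor_battery <- function(spec, n, seed) {
  stopifnot(inherits(spec, "factor_spec"))
  set.seed(seed)
  X <- rmvnorm_chol(n, spec$sigma)
  colnames(X) <- rownames(spec$loadings)
  X
}

#' Simulate factor scores and the battery they generate
#'
#' Like [simulate_factor_battery()] but also returns the latent factor
#' realizations, for recovery tests of factor scoring.
#'
#' @inheritParams simulate_factor_battery
#' @return list with elements `items` (n x p) and `factors` (n x k).
#' @export
simulate_factor_battery_with_truth <- function(spec, n, seed) {
  stopifnot(inherits(spec, "factor_spec"))
  set.seed(seed)
  k <- ncol(spec$loadings)
  Fz <- rmvnorm_chol(n, spec$phi)
  E <- matrix(stats::rnorm(n * nrow(spec$loadings)), n) %*%
    diag(sqrt(spec$uniquenesses), nrow(spec$loadings))
  X <- Fz %*% t(spec$loadings) + E
  colnames(X) <- rownames(spec$loadings)
  colnames(Fz) <- colnames(spec$loadings) %||% sprintf("F%d", seq_len(k))
  list(items = X, factors = Fz)
}

#' Specification of block-coherent parcel time series
#'
#' Parcels are partitioned into networks; samples over time are i.i.d.
#' Gaussian with a block correlation structure: `within_r` within a
#' network, `between_r` across networks.
#'
#' @param partition named character vector parcel_id -> network label.
#' @param within_r per-network target correlation; either a single value or
#'   a named vector over network labels.
#' @param between_r scalar between-network correlation (default 0).
#' @param timepoints samples per run.
#' @return object of class `timeseries_spec`.
#' @export
timeseries_spec <- function(partition, within_r, between_r = 0,
                            timepoints = 1200) {
  networks <- unique(unname(partition))
  if (length(within_r) == 1L && is.null(names(within_r)))
    within_r <- stats::setNames(rep(within_r, length(networks)), networks)
  nc_validate(all(networks %in% names(within_r)),
              "within_r must cover every network label")
  nc_validate(all(abs(within_r) < 1) && abs(between_r) < 1,
              "correlations must lie in (-1, 1)")
  p <- length(partition)
  lab <- unname(partition)
  sigma <- matrix(between_r, p, p)
  for (nw in networks) {
    idx <- which(lab == nw)
    sigma[idx, idx] <- within_r[[nw]]
  }
  diag(sigma) <- 1
  dimnames(sigma) <- list(names(partition), names(partition))
  nc_validate(is_pd(sigma), "implied parcel covariance is not positive definite")
  structure(list(partition = partition, within_r = within_r,
                 between_r = between_r, timepoints = timepoints,
                 sigma = sigma),
            class = "timeseries_spec")
}

#' Simulate per-subject parcel time series
#'
#' Each subject's parcel x timepoint matrix is drawn i.i.d. over time from
#' the block covariance implied by the spec.
#'
#' @param spec a [timeseries_spec()].
#' @param n_subjects number of subjects.
#' @param seed integer seed.
#' @return list of length `n_subjects`; each element a parcels x timepoints
#'   matrix with parcel ids as row names.
#' @export
simulate_parcel_timeseries <- function(spec, n_subjects, seed) {
  stopifnot(inherits(spec, "timeseries_spec"))
  lapply(seq_len(n_subjects), function(i) {
    set.seed(child_seed(seed, paste0("subject", i)))
    ts <- t(rmvnorm_chol(spec$timepoints, spec$sigma))
    rownames(ts) <- names(spec$partition)
    ts
  })
}

#' Discretize a latent severity into truncated symptom counts
#'
#' Maps each subject's latent severity to the number of thresholds lying
#' below it, yielding an integer severity in 0..5 that mimics truncated
#' DSM-IV symptom counts (abuse 0/1/2+ plus dependence 0/1/2/3+, top
#' category "5+").
#'
#' @param severity_latent numeric vector of latent severity values.
#' @param thresholds strictly increasing numeric vector of length 5.
#' @return integer vector in 0..5.
#' @export
simulate_symptom_counts <- function(severity_latent, thresholds) {
  nc_validate(length(thresholds) == 5, "exactly 5 thresholds required")
  nc_validate(all(diff(thresholds) > 0), "thresholds must be strictly increasing")
  counts <- vapply(severity_latent,
                   function(x) sum(thresholds < x), numeric(1))
  as.integer(counts)
}
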