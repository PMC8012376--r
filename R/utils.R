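#' @keywords internal
"_PACKAGE"

# Derive a reproducible 31-bit child seed from a master seed and a label.
# Polynomial string hash keeps the fan-out stable across platforms/sessions
# (no dependence on R's RNG state or on serialization internals).
child_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- as.double(seed %% 2147483647)
  for (cp in utf8ToInt(as.character(label))) {
    h <- (h * 31 + cp) %% 2147483647
  }
  as.integer(h)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Validation helper: stop with a consistent error class so callers/tests can
# distinguish bad input from internal failure.
nc_stop <- function(..., class = "neurocausal_error") {
  stop(errorCondition(paste0(...), class = c(class, "neurocausal_error")))
}

nc_validate <- function(ok, ...) {
  if (!ok) nc_stop(..., class = "neurocausal_validation_error")
  invisible(TRUE)
}

is_pd <- function(m, tol = 1e-10) {
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  all(ev > tol * max(abs(ev)))
}

# Draw n rows from N(0, sigma) with a fixed Cholesky-based scheme so output
# is deterministic given the seed.
rmvnorm_chol <- function(n, sigma) {
  p <- ncol(sigma)
  ch <- tryCatch(chol(sigma), error = function(e) {
    nc_stop("covariance matrix is not positive definite",
            class = "neurocausal_validation_error")
  })
  matrix(stats::rnorm(n * p), n, p) %*% ch
}

config_hash <- function(x) {
  # small stable fingerprint of a config list for provenance headers
  s <- paste(deparse(x[order(names(x))]), collapse = "")
  h <- 0
  for (cp in utf8ToInt(s)) h <- (h * 131 + cp) %% 2147483647
  sprintf("%08x", as.integer(h))
}
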