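# Decomposable Gaussian BIC ("SEM BIC") score. Higher is better. The local
# score of a node given its parents is
#   -n * log(sigma2_hat) - c * (|parents| + 1) * log(n)
# with sigma2_hat the ML residual variance of the least-squares regression
# of the child on its parents (intercept included). A graph's total score
# is the sum of local scores, and for Markov-equivalent DAGs on Gaussian
# data the totals agree (score equivalence), which is what greedy
# equivalence search relies on.

# Precompute sufficient statistics once per dataset.
score_cache <- function(data, penalty_discount) {
  data <- as.matrix(data)
  if (!is.numeric(data)) nc_stop("non-numeric data",
                                 class = "neurocausal_validation_error")
  n <- nrow(data)
  xc <- scale(data, center = TRUE, scale = FALSE)
  S <- crossprod(xc) / n # ML covariance
  env <- new.env(parent = emptyenv())
  p <- ncol(S)
  list(S = S, n = n, c = penalty_discount, nodes = colnames(data),
       cache = env,
       # exact double-precision bitmask keys for parent sets (p <= 40)
       pow = if (p <= 40) 2^(seq_len(p) - 1) else NULL)
}

local_score_idx <- function(sc, child, parents) {
  key <- if (!is.null(sc$pow)) {
    sprintf("%.0f", child + length(sc$pow) * sum(sc$pow[parents]))
  } else {
    paste0(child, "|", paste(sort(parents), collapse = ","))
  }
  hit <- sc$cache[[key]]
  if (!is.null(hit)) return(hit)
  S <- sc$S
  n <- sc$n
  if (length(parents)) {
    Sxx <- S[parents, parents, drop = FALSE]
    Sxy <- S[parents, child, drop = FALSE]
    beta <- tryCatch(solve(Sxx, Sxy), error = function(e) {
      nc_stop("singular design for child ", sc$nodes[child],
              " with parents {",
              paste(sc$nodes[parents], collapse = ", "), "}",
              class = "neurocausal_validation_error")
    })
    sigma2 <- S[child, child] - drop(crossprod(Sxy, beta))
  } else {
    sigma2 <- S[child, child]
  }
  sigma2 <- max(sigma2, 1e-12)
  val <- -n * log(sigma2) - sc$c * (length(parents) + 1) * log(n)
  sc$cache[[key]] <- val
  val
}

#' Local Gaussian BIC score of a child given a parent set
#'
#' @param data subjects x variables numeric matrix.
#' @param child child variable name.
#' @param parents character vector of parent names (excluding the child).
#' @param penalty_discount multiplier `c` on the BIC complexity penalty.
#' @return the local score (higher is better).
#' @export
sem_bic_local_score <- function(data, child, parents = character(),
                                penalty_discount = 2) {
  nc_validate(!(child %in% parents), "parents must exclude the child")
  nc_validate(nrow(data) > length(parents) + 2,
              "need n > |parents| + 2 observations")
  sc <- score_cache(data, penalty_discount)
  ci <- match(child, sc$nodes)
  pi <- match(parents, sc$nodes)
  nc_validate(!anyNA(c(ci, pi)), "unknown variable name")
  local_score_idx(sc, ci, sort(pi))
}

#' Total BIC score of a DAG
#'
#' Sum of [sem_bic_local_score()] over nodes; used by the exhaustive-search
#' oracle in tests.
#'
#' @param data data matrix.
#' @param amat endpoint-mark matrix of a DAG.
#' @param penalty_discount BIC penalty multiplier.
#' @export
dag_total_score <- function(data, amat, penalty_discount = 2) {
  sc <- score_cache(data, penalty_discount)
  sum(vapply(seq_len(nrow(amat)), function(v) {
    local_score_idx(sc, v, sort(mg_parents(amat, v)))
  }, numeric(1)))
}
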