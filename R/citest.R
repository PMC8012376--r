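#' Fisher-z conditional independence test
#'
#' Tests x independent of y given the set S under a Gaussian model: the
#' partial correlation of x and y given S is computed by inverting the
#' correlation submatrix over {x, y} union S, transformed with Fisher's z,
#' and scaled by sqrt(n - |S| - 3) to a standard-normal statistic.
#'
#' @param data subjects x variables numeric matrix, or a prebuilt
#'   sufficient-statistics object from [ci_suffstat()].
#' @param x,y variable names.
#' @param S character vector of conditioning variable names.
#' @param alpha significance level; independence is declared when
#'   p > alpha.
#' @return list with `statistic`, `p_value`, `independent`, `partial_r`.
#' @export
fisher_z_ci_test <- function(data, x, y, S = character(), alpha = 0.01) {
  st <- if (is.list(data) && !is.null(data$R)) data else ci_suffstat(data)
  xi <- match(x, st$nodes); yi <- match(y, st$nodes)
  Si <- match(S, st$nodes)
  nc_validate(!anyNA(c(xi, yi, Si)), "unknown variable name")
  nc_validate(!(xi %in% Si) && !(yi %in% Si), "x and y must not be in S")
  nc_validate(st$n - length(Si) - 3 > 0, "n - |S| - 3 must be positive")
  r <- partial_correlation_idx(st$R, xi, yi, Si)
  stat <- sqrt(st$n - length(Si) - 3) * abs(atanh(min(max(r, -1 + 1e-12),
                                                      1 - 1e-12)))
  p <- 2 * stats::pnorm(stat, lower.tail = FALSE)
  list(statistic = stat, p_value = p, independent = p > alpha,
       partial_r = r)
}

#' @rdname fisher_z_ci_test
#' @export
ci_suffstat <- function(data) {
  data <- as.matrix(data)
  list(R = correlation_matrix(data), n = nrow(data), nodes = colnames(data))
}

partial_correlation_idx <- function(R, x, y, S) {
  idx <- c(x, y, S)
  P <- tryCatch(solve(R[idx, idx, drop = FALSE]), error = function(e) {
    nc_stop("singular conditioning submatrix",
            class = "neurocausal_validation_error")
  })
  -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
}
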