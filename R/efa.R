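#' Pearson correlation matrix of a data matrix
#'
#' @param data numeric subjects x variables matrix.
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(data) {
  data <- as.matrix(data)
  nc_validate(nrow(data) >= 2, "need at least 2 subjects")
  sds <- apply(data, 2, stats::sd)
  if (any(sds == 0)) {
    bad <- colnames(data)[sds == 0] %||% which(sds == 0)
    nc_stop("constant column(s): ", paste(bad, collapse = ", "),
            class = "neurocausal_validation_error")
  }
  R <- stats::cor(data)
  (R + t(R)) / 2
}

#' Monte-Carlo parallel analysis for factor retention
#'
#' Compares the observed eigenvalues of the item correlation matrix with a
#' null distribution obtained by independently permuting each column's rows
#' (breaking all inter-item dependence while preserving marginals) and
#' recomputing the eigenvalues. The number of significant factors is the
#' largest k such that eigenvalues 1..k all have permutation p-values below
#' `alpha_pa`.
#'
#' @param data subjects x items numeric matrix.
#' @param n_perm number of Monte-Carlo replicates (>= 100 recommended).
#' @param alpha_pa significance level for eigenvalue retention.
#' @param seed integer seed.
#' @param null `"permutation"` (default) or `"normal"`; the latter draws
#'   null data from independent standard normals of the same dimensions.
#' @return object of class `parallel_analysis_result` with observed
#'   eigenvalues, per-index null quantiles and p-values, and selected `k`.
#' @export
parallel_analysis <- function(data, n_perm = 100, alpha_pa = 0.05, seed = 1,
                              null = c("permutation", "normal")) {
  null <- match.arg(null)
  nc_validate(n_perm >= 1, "n_perm must be at least 1")
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  obs <- eigen(correlation_matrix(data), symmetric = TRUE,
               only.values = TRUE)$values
  set.seed(seed)
  nulls <- matrix(0, n_perm, p)
  for (b in seq_len(n_perm)) {
    perm <- if (null == "permutation") {
      apply(data, 2, sample)
    } else {
      matrix(stats::rnorm(n * p), n, p)
    }
    nulls[b, ] <- eigen(stats::cor(perm), symmetric = TRUE,
                        only.values = TRUE)$values
  }
  pvals <- vapply(seq_len(p), function(i) mean(nulls[, i] >= obs[i]),
                  numeric(1))
  below <- pvals < alpha_pa
  k <- if (below[1]) which.min(c(below, FALSE)) - 1L else 0L
  structure(list(observed = obs,
                 null_quantiles = apply(nulls, 2, stats::quantile,
                                        probs = c(0.5, 0.95, 0.99)),
                 null_mean = colMeans(nulls),
                 p_values = pvals, k = as.integer(k),
                 alpha_pa = alpha_pa, n_perm = n_perm, null = null,
                 seed = seed),
            class = "parallel_analysis_result")
}

#' @export
print.parallel_analysis_result <- function(x, ...) {
  cat("Parallel analysis (", x$null, " null, ", x$n_perm, " replicates)\n",
      sep = "")
  cat("Selected factors: k =", x$k, "at alpha =", x$alpha_pa, "\n")
  invisible(x)
}

# EM iteration for maximum-likelihood factor analysis of a correlation
# matrix. Sufficient-statistic form: with Sigma = Lambda Lambda' + Psi,
#   beta  = Lambda' Sigma^{-1}
#   Cxz   = R beta'                  (expected item-factor cross-moments)
#   Czz   = beta R beta' + I - beta Lambda
#   Lambda <- Cxz Czz^{-1},  Psi <- diag(R - Lambda Cxz')
# Woodbury keeps each step O(p^2 k).
em_factanal <- function(R, k, max_iter = 10000, tol = 1e-12,
                        psi_floor = 1e-3) {
  p <- ncol(R)
  logdetR <- determinant(R, logarithm = TRUE)$modulus
  # principal-factor start from squared multiple correlations
  smc <- 1 - 1 / diag(solve(R))
  psi <- pmax(1 - smc, psi_floor)
  ed <- eigen(R - diag(psi, p), symmetric = TRUE)
  L <- ed$vectors[, seq_len(k), drop = FALSE] %*%
    diag(sqrt(pmax(ed$values[seq_len(k)], 1e-8)), k)
  f_old <- Inf
  heywood <- FALSE
  converged <- FALSE
  iters <- 0L
  for (it in seq_len(max_iter)) {
    iters <- it
    # Sigma^{-1} via Woodbury with diagonal Psi
    Lp <- L / psi                       # Psi^{-1} Lambda
    M <- diag(k) + crossprod(L, Lp)     # I + L' Psi^{-1} L
    beta <- t(Lp %*% solve(M))          # Lambda' Sigma^{-1}, k x p
    Cxz <- R %*% t(beta)
    Czz <- beta %*% Cxz + diag(k) - beta %*% L
    L_new <- Cxz %*% solve(Czz)
    psi_new <- diag(R) - rowSums(L_new * Cxz)
    if (any(psi_new < psi_floor)) {
      heywood <- TRUE
      psi_new <- pmax(psi_new, psi_floor)
    }
    L <- L_new
    psi <- psi_new
    # ML discrepancy F = log|Sigma| + tr(R Sigma^{-1}) - log|R| - p
    Lp <- L / psi
    M <- diag(k) + crossprod(L, Lp)
    logdetS <- determinant(M, logarithm = TRUE)$modulus + sum(log(psi))
    SinvR <- R / psi - (Lp %*% solve(M)) %*% (crossprod(Lp, R))
    f <- as.numeric(logdetS + sum(diag(SinvR)) - logdetR - p)
    if (is.finite(f_old) && abs(f_old - f) < tol * (abs(f) + tol)) {
      converged <- TRUE
      f_old <- f
      break
    }
    f_old <- f
  }
  if (!converged && iters >= max_iter) {
    # report, do not fail: EM progress is monotone so the last iterate is
    # still the best visited
    warning("EM did not reach tolerance after ", max_iter, " iterations")
  }
  list(loadings = L, uniquenesses = psi, f = f_old, heywood = heywood,
       iterations = iters, converged = converged)
}

# flip loading columns so the entry largest in magnitude is positive
sign_normalize <- function(L, phi) {
  s <- vapply(seq_len(ncol(L)), function(j) {
    sign(L[which.max(abs(L[, j])), j])
  }, numeric(1))
  s[s == 0] <- 1
  list(loadings = L %*% diag(s, ncol(L)),
       phi = diag(s, ncol(L)) %*% phi %*% diag(s, ncol(L)))
}

#' Maximum-likelihood exploratory factor analysis with oblimin rotation
#'
#' Extracts `k` factors from the item correlation matrix by maximum
#' likelihood (EM algorithm), rotates obliquely with direct quartimin
#' (oblimin, gamma = 0) by gradient projection, and reports the
#' Bartlett-corrected chi-square, RMSEA and TLI. Loading columns are
#' ordered by explained common variance and sign-normalized so the largest
#' loading in each column is positive.
#'
#' @param data subjects x items numeric matrix.
#' @param k number of factors; must be below the Ledermann bound.
#' @param rotate `"oblimin"` (default) or `"none"`.
#' @param max_iter,tol EM iteration cap and relative tolerance on the ML
#'   discrepancy.
#' @return object of class `factor_model`: rotated pattern `loadings`,
#'   factor correlations `phi`, `uniquenesses`, `f_ml`, `chisq`, `df`,
#'   `p_value`, `rmsea`, `tli`, `variance` (see [variance_explained()]),
#'   `heywood` flag, `n`, and the unrotated solution.
#' @export
fit_efa <- function(data, k, rotate = c("oblimin", "none"),
                    max_iter = 10000, tol = 1e-12) {
  rotate <- match.arg(rotate)
  data <- as.matrix(data)
  n <- nrow(data); p <- ncol(data)
  nc_validate(k >= 1, "k must be at least 1")
  ledermann <- floor((2 * p + 1 - sqrt(8 * p + 1)) / 2)
  nc_validate(k <= ledermann,
              "k = ", k, " exceeds the Ledermann bound (", ledermann,
              ") for p = ", p, " items")
  R <- correlation_matrix(data)
  em <- em_factanal(R, k, max_iter = max_iter, tol = tol)
  L0 <- em$loadings
  rownames(L0) <- colnames(data)
  colnames(L0) <- sprintf("F%d", seq_len(k))
  if (rotate == "oblimin" && k > 1) {
    rot <- rotate_oblimin(L0)
    L <- rot$loadings
    phi <- rot$phi
  } else {
    L <- L0
    phi <- diag(k)
  }
  # order factors by explained common variance, then fix signs
  contrib <- diag(t(L) %*% L %*% phi)
  ordv <- order(contrib, decreasing = TRUE)
  L <- L[, ordv, drop = FALSE]
  phi <- phi[ordv, ordv, drop = FALSE]
  sn <- sign_normalize(L, phi)
  L <- sn$loadings
  phi <- sn$phi
  colnames(L) <- sprintf("F%d", seq_len(k))
  dimnames(phi) <- list(colnames(L), colnames(L))
  # Bartlett-corrected likelihood-ratio statistic and fit indices
  df <- ((p - k)^2 - p - k) / 2
  cmult <- n - 1 - (2 * p + 5) / 6 - 2 * k / 3
  chisq <- max(cmult * em$f, 0)
  logdetR <- as.numeric(determinant(R, logarithm = TRUE)$modulus)
  chisq_null <- -(n - 1 - (2 * p + 5) / 6) * logdetR
  df_null <- p * (p - 1) / 2
  rmsea_val <- if (df > 0) rmsea(chisq, df, n) else NA_real_
  tli_val <- if (df > 0) tli(chisq, df, chisq_null, df_null) else NA_real_
  model <- structure(list(
    loadings = L, phi = phi,
    uniquenesses = stats::setNames(em$uniquenesses, colnames(data)),
    f_ml = em$f, chisq = chisq, df = df,
    p_value = if (df > 0) stats::pchisq(chisq, df, lower.tail = FALSE) else NA_real_,
    chisq_null = chisq_null, df_null = df_null,
    rmsea = rmsea_val, tli = tli_val,
    heywood = em$heywood, em_iterations = em$iterations,
    em_converged = em$converged,
    unrotated = L0, rotation = rotate, n = n,
    variables = colnames(data)), class = "factor_model")
  model$variance <- variance_explained(model)
  model
}

#' @export
print.factor_model <- function(x, ...) {
  cat("ML factor model:", length(x$variables), "items,",
      ncol(x$loadings), "factors (", x$rotation, "rotation )\n")
  cat(sprintf("chisq(%d) = %.2f, RMSEA = %.3f, TLI = %.3f\n",
              x$df, x$chisq, x$rmsea, x$tli))
  if (x$heywood) cat("note: Heywood case, uniqueness(es) floored\n")
  invisible(x)
}

#' Per-factor and cumulative proportion of common variance
#'
#' Factor j's contribution is the sum over items of pattern x structure
#' loadings, i.e. `diag(L' L Phi)`; contributions sum exactly to the total
#' communality, so proportions are of common (not total) variance.
#'
#' @param model a [fit_efa()] result.
#' @return data frame with `factor`, `ss_loading`, `proportion`,
#'   `cumulative`.
#' @export
variance_explained <- function(model) {
  L <- model$loadings
  contrib <- diag(t(L) %*% L %*% model$phi)
  prop <- contrib / sum(contrib)
  data.frame(factor = colnames(L), ss_loading = contrib,
             proportion = prop, cumulative = cumsum(prop),
             row.names = NULL)
}

#' Factor scores for a fitted model
#'
#' Regression (Thurstone) scores by default: standardized data times
#' \eqn{R^{-1} \Lambda \Phi}; the Bartlett weighted-least-squares
#' alternative is available. Score columns are standardized.
#'
#' @param model a [fit_efa()] result.
#' @param data the data the model was fitted on (same variables).
#' @param method `"regression"` (default) or `"bartlett"`.
#' @return subjects x k matrix of standardized factor scores.
#' @export
factor_scores <- function(model, data, method = c("regression", "bartlett")) {
  method <- match.arg(method)
  data <- as.matrix(data)
  nc_validate(identical(colnames(data), model$variables),
              "data variables do not match the fitted model")
  Z <- scale(data)
  L <- model$loadings
  if (method == "regression") {
    R <- correlation_matrix(data)
    W <- solve(R, L %*% model$phi)
  } else {
    Lp <- L / model$uniquenesses
    W <- Lp %*% solve(crossprod(L, Lp))
  }
  S <- Z %*% W
  S <- scale(S)
  attr(S, "scaled:center") <- NULL
  attr(S, "scaled:scale") <- NULL
  colnames(S) <- colnames(L)
  S
}
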