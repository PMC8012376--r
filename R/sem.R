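#' Root mean square error of approximation
#'
#' @param chi2 model chi-square.
#' @param df model degrees of freedom (>= 1).
#' @param n sample size (>= 2).
#' @return `sqrt(max(chi2 - df, 0) / (df * (n - 1)))`.
#' @export
rmsea <- function(chi2, df, n) {
  if (df < 1) nc_stop("RMSEA undefined for df = 0",
                      class = "neurocausal_domain_error")
  nc_validate(n >= 2, "n must be at least 2")
  sqrt(max(chi2 - df, 0) / (df * (n - 1)))
}

#' Tucker-Lewis index
#'
#' @param chi2,df model chi-square and degrees of freedom.
#' @param chi2_null,df_null baseline (independence) model chi-square and
#'   degrees of freedom.
#' @return `((chi2_null/df_null) - (chi2/df)) / ((chi2_null/df_null) - 1)`.
#' @export
tli <- function(chi2, df, chi2_null, df_null) {
  nc_validate(df >= 1 && df_null >= 1, "df and df_null must be >= 1")
  ratio_null <- chi2_null / df_null
  if (abs(ratio_null - 1) < 1e-12) {
    nc_stop("degenerate baseline: chi2_null/df_null = 1",
            class = "neurocausal_domain_error")
  }
  (ratio_null - chi2 / df) / (ratio_null - 1)
}

#' Translate a PAG into a linear SEM specification
#'
#' Translation rules: `A --> B` becomes the regression B on A; `A o-> B`
#' likewise (the circle is read as a tail); `A <-> B` and `A o-o B`
#' become residual covariances (with `drop_circle_circle = TRUE`, `o-o`
#' edges are dropped instead). A per-edge translation log records the rule
#' applied. Translation that would create a directed cycle is an error.
#'
#' @param graph a `pag` (or `cpdag`; undirected edges map to residual
#'   covariances).
#' @param drop_circle_circle drop `o-o` edges instead of mapping them to
#'   residual covariances.
#' @param on_cycle what to do when the translated regressions contain a
#'   directed cycle (possible in finite samples when conditional
#'   independence decisions are mutually inconsistent): `"error"`
#'   (default) aborts listing the cycle; `"covariance"` deterministically
#'   demotes one cycle edge (preferring circle-arrow edges, then
#'   lexicographic order) to a residual covariance until the regressions
#'   are acyclic, logging each demotion.
#' @return object of class `sem_spec` with `regressions` (child, parent),
#'   `covariances` (a, b), `variables`, and `log`.
#' @export
pag_to_sem_spec <- function(graph, drop_circle_circle = FALSE,
                            on_cycle = c("error", "covariance")) {
  on_cycle <- match.arg(on_cycle)
  ed <- graph_edges(graph)
  reg <- list(); cov <- list(); log <- list()
  for (r in seq_len(nrow(ed))) {
    a <- ed$from[r]; b <- ed$to[r]
    ma <- ed$mark_from[r]; mb <- ed$mark_to[r]
    rule <- NULL
    if (mb == "arrow" && ma %in% c("tail", "circle")) {
      reg <- c(reg, list(c(child = b, parent = a)))
      rule <- if (ma == "tail") "directed -> regression"
              else "circle-arrow -> regression (circle as tail)"
    } else if (ma == "arrow" && mb %in% c("tail", "circle")) {
      reg <- c(reg, list(c(child = a, parent = b)))
      rule <- if (mb == "tail") "directed -> regression"
              else "circle-arrow -> regression (circle as tail)"
    } else if (ma == "arrow" && mb == "arrow") {
      cov <- c(cov, list(c(a = a, b = b)))
      rule <- "bidirected -> residual covariance"
    } else if (ma == "circle" && mb == "circle") {
      if (drop_circle_circle) {
        rule <- "circle-circle -> dropped"
      } else {
        cov <- c(cov, list(c(a = a, b = b)))
        rule <- "circle-circle -> residual covariance"
      }
    } else {
      cov <- c(cov, list(c(a = a, b = b)))
      rule <- "undirected -> residual covariance"
    }
    log <- c(log, list(data.frame(from = a, to = b, edge = ed$edge[r],
                                  rule = rule)))
  }
  regressions <- if (length(reg)) {
    as.data.frame(do.call(rbind, reg), stringsAsFactors = FALSE)
  } else data.frame(child = character(), parent = character())
  covariances <- if (length(cov)) {
    as.data.frame(do.call(rbind, cov), stringsAsFactors = FALSE)
  } else data.frame(a = character(), b = character())
  spec <- structure(list(regressions = regressions,
                         covariances = covariances,
                         variables = graph$nodes,
                         log = if (length(log)) do.call(rbind, log)
                               else data.frame(from = character(),
                                               to = character(),
                                               edge = character(),
                                               rule = character())),
                    class = "sem_spec")
  repeat {
    cyc <- find_regression_cycle(spec)
    if (is.null(cyc)) break
    if (on_cycle == "error") {
      nc_stop("translation creates a directed cycle: ",
              paste(cyc, collapse = " -> "),
              class = "neurocausal_structural_error")
    }
    spec <- demote_cycle_edge(spec, cyc)
  }
  spec
}

check_spec_acyclic <- function(spec) {
  cyc <- find_regression_cycle(spec)
  if (!is.null(cyc)) {
    nc_stop("regressions contain a directed cycle: ",
            paste(cyc, collapse = " -> "),
            class = "neurocausal_structural_error")
  }
  invisible(TRUE)
}

# first directed cycle in the regression graph (as a node sequence), or
# NULL; DFS with deterministic (sorted) neighbor order
find_regression_cycle <- function(spec) {
  reg <- spec$regressions
  if (!nrow(reg)) return(NULL)
  children <- function(v) sort(reg$child[reg$parent == v])
  color <- stats::setNames(rep(0L, length(spec$variables)), spec$variables)
  stack <- character(0)
  result <- NULL
  visit <- function(v) {
    if (!is.null(result)) return()
    color[[v]] <<- 1L
    stack <<- c(stack, v)
    for (w in children(v)) {
      if (!is.null(result)) break
      if (color[[w]] == 1L) {
        i <- match(w, stack)
        result <<- c(stack[i:length(stack)], w)
      } else if (color[[w]] == 0L) {
        visit(w)
      }
    }
    stack <<- stack[-length(stack)]
    color[[v]] <<- 2L
  }
  for (v in sort(unique(reg$parent))) {
    if (color[[v]] == 0L) visit(v)
    if (!is.null(result)) break
  }
  result
}

# demote one regression on the cycle to a residual covariance: prefer
# edges translated from circle-arrow marks, then lexicographic order
demote_cycle_edge <- function(spec, cyc) {
  reg <- spec$regressions
  on_cyc <- which(reg$parent %in% cyc & reg$child %in% cyc &
                    match(reg$parent, cyc) + 1L ==
                    match(reg$child, cyc))
  # also catch the wrap-around edge
  stopifnot(length(on_cyc) >= 1)
  rule_of <- function(i) {
    hit <- spec$log$rule[(spec$log$from == reg$parent[i] &
                            spec$log$to == reg$child[i]) |
                           (spec$log$from == reg$child[i] &
                              spec$log$to == reg$parent[i])]
    if (length(hit)) hit[1] else ""
  }
  weak <- on_cyc[grepl("circle", vapply(on_cyc, rule_of, character(1)))]
  pool <- if (length(weak)) weak else on_cyc
  ordp <- order(reg$parent[pool], reg$child[pool])
  pick <- pool[ordp[1]]
  demoted <- reg[pick, ]
  spec$regressions <- reg[-pick, , drop = FALSE]
  spec$covariances <- rbind(spec$covariances,
                            data.frame(a = demoted$parent,
                                       b = demoted$child))
  spec$log <- rbind(spec$log,
                    data.frame(from = demoted$parent, to = demoted$child,
                               edge = paste(demoted$parent, "-->",
                                            demoted$child),
                               rule = "cycle -> demoted to residual covariance"))
  spec
}

#' Directly construct a SEM specification
#'
#' @param variables all observed variables.
#' @param regressions data frame with `child`, `parent` columns.
#' @param covariances data frame with `a`, `b` columns (residual
#'   covariances).
#' @export
sem_spec <- function(variables, regressions = NULL, covariances = NULL) {
  spec <- structure(list(
    regressions = regressions %||% data.frame(child = character(),
                                              parent = character()),
    covariances = covariances %||% data.frame(a = character(),
                                              b = character()),
    variables = variables,
    log = data.frame(from = character(), to = character(),
                     edge = character(), rule = character())),
    class = "sem_spec")
  check_spec_acyclic(spec)
  spec
}

numeric_gradient <- function(f, x, eps = 1e-6) {
  vapply(seq_along(x), function(i) {
    xp <- x; xm <- x
    xp[i] <- xp[i] + eps
    xm[i] <- xm[i] - eps
    (f(xp) - f(xm)) / (2 * eps)
  }, numeric(1))
}

# implied covariance for parameter vector theta
sem_implied <- function(theta, layout) {
  p <- layout$p
  B <- matrix(0, p, p)
  if (nrow(layout$reg_idx)) {
    B[layout$reg_idx] <- theta[seq_len(nrow(layout$reg_idx))]
  }
  psi <- diag(exp(theta[layout$var_pos]), p)
  if (nrow(layout$cov_idx)) {
    cv <- theta[layout$cov_pos]
    psi[layout$cov_idx] <- cv
    psi[layout$cov_idx[, c(2, 1), drop = FALSE]] <- cv
  }
  IB <- diag(p) - B
  IBi <- solve(IB)
  IBi %*% psi %*% t(IBi)
}

#' Fit a linear SEM by Gaussian maximum likelihood
#'
#' Covariance-only ML: minimizes the discrepancy
#' \eqn{F = \log|\Sigma(\theta)| + tr(S\Sigma^{-1}(\theta)) - \log|S| - p}
#' over regression coefficients, residual variances and residual
#' covariances; \eqn{\chi^2 = (n-1) F} at the optimum. Standard errors
#' come from the inverse observed information; standardized weights from
#' the model-implied standard deviations.
#'
#' @param spec a [sem_spec()] / [pag_to_sem_spec()] specification.
#' @param data subjects x variables matrix containing `spec$variables`.
#' @return object of class `sem_result`: `edges` (per-edge estimates,
#'   standardized weights, SE, z, p), `chisq`, `df`, `chisq_null`,
#'   `df_null`, `rmsea`, `tli`, `n`, `implied`, `admissible`, `converged`.
#' @export
fit_sem <- function(spec, data) {
  data <- as.matrix(data)
  vars <- spec$variables
  nc_validate(all(vars %in% colnames(data)),
              "spec variables missing from data: ",
              paste(setdiff(vars, colnames(data)), collapse = ", "))
  X <- data[, vars, drop = FALSE]
  n <- nrow(X)
  p <- length(vars)
  S <- stats::cov(X)
  reg_idx <- cbind(match(spec$regressions$child, vars),
                   match(spec$regressions$parent, vars))
  cov_idx <- cbind(match(spec$covariances$a, vars),
                   match(spec$covariances$b, vars))
  n_reg <- nrow(spec$regressions)
  n_cov <- nrow(spec$covariances)
  n_free <- n_reg + p + n_cov
  nc_validate(n > n_free, "need n greater than the free parameter count")
  df <- p * (p + 1) / 2 - n_free
  nc_validate(df >= 0, "model has more free parameters than moments")
  layout <- list(p = p, reg_idx = reg_idx, cov_idx = cov_idx,
                 var_pos = n_reg + seq_len(p),
                 cov_pos = n_reg + p + seq_len(n_cov))

  # start values: per-equation OLS, residual variances from the residuals
  theta0 <- numeric(n_free)
  resid_var <- diag(S)
  for (ch in unique(spec$regressions$child)) {
    rows <- which(spec$regressions$child == ch)
    pa <- spec$regressions$parent[rows]
    b <- solve(S[pa, pa, drop = FALSE], S[pa, ch])
    theta0[rows] <- b
    resid_var[ch] <- max(S[ch, ch] - drop(crossprod(S[pa, ch], b)), 1e-4)
  }
  theta0[layout$var_pos] <- log(resid_var[vars])
  if (n_cov) theta0[layout$cov_pos] <- 0

  logdetS <- as.numeric(determinant(S, logarithm = TRUE)$modulus)
  fml <- function(theta) {
    sigma <- sem_implied(theta, layout)
    ch <- tryCatch(chol(sigma), error = function(e) NULL)
    if (is.null(ch)) return(1e10) # outside the PD cone
    val <- 2 * sum(log(diag(ch))) + sum(S * chol2inv(ch)) - logdetS - p
    if (!is.finite(val)) 1e10 else val
  }
  opt <- stats::optim(theta0, fml, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-14))
  if (opt$convergence != 0) {
    g <- tryCatch(max(abs(numeric_gradient(fml, opt$par))),
                  error = function(e) NA_real_)
    nc_stop("SEM optimization did not converge (code ", opt$convergence,
            ", gradient norm ", format(g), ")",
            class = "neurocausal_convergence_error")
  }
  theta <- opt$par
  sigma <- sem_implied(theta, layout)
  dimnames(sigma) <- list(vars, vars)

  # observed information: cov(theta) = (2 / (n - 1)) H^{-1}
  H <- stats::optimHess(theta, fml)
  cov_theta <- tryCatch(2 / (n - 1) * solve(H), error = function(e) {
    matrix(NA_real_, n_free, n_free)
  })
  se <- sqrt(pmax(diag(cov_theta), 0))

  sds <- sqrt(diag(sigma))
  edges <- NULL
  if (n_reg) {
    est <- theta[seq_len(n_reg)]
    std <- est * sds[reg_idx[, 2]] / sds[reg_idx[, 1]]
    se_r <- se[seq_len(n_reg)]
    z <- est / se_r
    edges <- data.frame(from = spec$regressions$parent,
                        to = spec$regressions$child,
                        type = "regression", estimate = est,
                        std_weight = std, se = se_r, z = z,
                        p = 2 * stats::pnorm(-abs(z)))
  }
  if (n_cov) {
    est <- theta[layout$cov_pos]
    std <- est / (sds[cov_idx[, 1]] * sds[cov_idx[, 2]])
    se_c <- se[layout$cov_pos]
    z <- est / se_c
    edges <- rbind(edges,
                   data.frame(from = spec$covariances$a,
                              to = spec$covariances$b,
                              type = "covariance", estimate = est,
                              std_weight = std, se = se_c, z = z,
                              p = 2 * stats::pnorm(-abs(z))))
  }
  if (is.null(edges)) {
    edges <- data.frame(from = character(), to = character(),
                        type = character(), estimate = numeric(),
                        std_weight = numeric(), se = numeric(),
                        z = numeric(), p = numeric())
  }

  chisq <- max((n - 1) * opt$value, 0)
  R <- stats::cov2cor(S)
  chisq_null <- -(n - 1) *
    as.numeric(determinant(R, logarithm = TRUE)$modulus)
  df_null <- p * (p - 1) / 2
  psi <- diag(exp(theta[layout$var_pos]), p)
  if (n_cov) {
    cv <- theta[layout$cov_pos]
    psi[cov_idx] <- cv
    psi[cov_idx[, c(2, 1), drop = FALSE]] <- cv
  }
  admissible <- is_pd(psi, tol = 1e-12) && is_pd(sigma, tol = 1e-12)
  structure(list(edges = edges, chisq = chisq, df = df,
                 chisq_null = chisq_null, df_null = df_null,
                 rmsea = if (df >= 1) rmsea(chisq, df, n) else NA_real_,
                 tli = if (df >= 1) tli(chisq, df, chisq_null, df_null)
                       else NA_real_,
                 n = n, f_ml = opt$value, implied = sigma,
                 admissible = admissible, converged = TRUE,
                 spec = spec),
            class = "sem_result")
}

#' @export
print.sem_result <- function(x, ...) {
  cat(sprintf("SEM fit: chisq(%d) = %.2f, RMSEA = %.3f, TLI = %.3f, n = %d\n",
              x$df, x$chisq, x$rmsea, x$tli, x$n))
  if (!x$admissible) cat("note: solution flagged inadmissible\n")
  print(x$edges, digits = 3)
  invisible(x)
}

#' Simulate data from a fitted SEM
#'
#' Draws multivariate-normal data with the model-implied covariance of a
#' fitted SEM; used for parameter-recovery checks and parametric
#' refitting.
#'
#' @param result a [fit_sem()] result.
#' @param n number of rows.
#' @param seed integer seed.
#' @return numeric matrix with the spec's variables as columns.
#' @export
simulate_sem_result <- function(result, n, seed) {
  set.seed(seed)
  x <- rmvnorm_chol(n, result$implied)
  colnames(x) <- colnames(result$implied)
  x
}

#' Write SEM results as an edge table and JSON fit block
#'
#' @param result a [fit_sem()] result.
#' @param prefix output prefix; writes `<prefix>_edges.tsv` and
#'   `<prefix>_fit.json`.
#' @param provenance optional character vector of `#` header lines for the
#'   edge table.
#' @export
write_sem_result <- function(result, prefix, provenance = NULL) {
  edge_path <- paste0(prefix, "_edges.tsv")
  con <- file(edge_path, "w")
  if (length(provenance)) writeLines(paste0("# ", provenance), con)
  utils::write.table(result$edges, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  close(con)
  jsonlite::write_json(
    list(chisq = result$chisq, df = result$df, rmsea = result$rmsea,
         tli = result$tli, n = result$n,
         chisq_null = result$chisq_null, df_null = result$df_null,
         admissible = result$admissible,
         provenance = as.list(provenance)),
    paste0(prefix, "_fit.json"), auto_unbox = TRUE, digits = NA)
  invisible(prefix)
}
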