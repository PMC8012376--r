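#' Combine truncated abuse and dependence symptom counts
#'
#' AUD severity is the sum of the truncated DSM-IV alcohol-abuse count
#' (0, 1, 2+) and alcohol-dependence count (0, 1, 2, 3+), giving an
#' integer severity from 0 to 5.
#'
#' @param abuse integer(s) in {0, 1, 2}.
#' @param dependence integer(s) in {0, 1, 2, 3}.
#' @return integer severity in 0..5.
#' @export
combine_symptom_counts <- function(abuse, dependence) {
  nc_validate(all(abuse %in% 0:2), "abuse count must be 0, 1 or 2")
  nc_validate(all(dependence %in% 0:3), "dependence count must be 0..3")
  as.integer(abuse + dependence)
}

#' Pearson chi-square test for a contingency table
#'
#' Plain Pearson statistic without continuity correction:
#' \eqn{\sum (O - E)^2 / E} with expected counts from the margins.
#'
#' @param table counts matrix (r x c), all entries non-negative, all
#'   margins positive.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
contingency_chi2 <- function(table) {
  table <- as.matrix(table)
  nc_validate(all(table >= 0), "counts must be non-negative")
  rs <- rowSums(table); cs <- colSums(table)
  nc_validate(all(rs > 0) && all(cs > 0), "zero row or column margin")
  E <- outer(rs, cs) / sum(table)
  stat <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

# pooled-variance two-sample t statistic
pooled_t <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / (nx + ny - 2)
  tval <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  df <- nx + ny - 2
  list(statistic = tval, df = df,
       p_value = 2 * stats::pt(-abs(tval), df))
}

#' Per-group descriptives with group contrasts
#'
#' For each numeric column: per-group n, mean, SD and (for two groups) a
#' pooled-variance t test. For each categorical column: per-group counts
#' and a Pearson chi-square test.
#'
#' @param data data frame.
#' @param group name of the grouping column.
#' @return list with `groups`, `continuous` (data frame), `categorical`
#'   (list of count tables with test results).
#' @export
describe_sample <- function(data, group) {
  nc_validate(group %in% names(data), "grouping column not found: ", group)
  g <- factor(data[[group]])
  lv <- levels(g)
  two <- length(lv) == 2
  if (length(lv) < 2) warning("single group: contrasts omitted")
  cont <- NULL
  catg <- list()
  for (v in setdiff(names(data), group)) {
    x <- data[[v]]
    if (is.numeric(x)) {
      row <- data.frame(variable = v)
      for (l in lv) {
        row[[paste0("n_", l)]] <- sum(g == l)
        row[[paste0("mean_", l)]] <- mean(x[g == l])
        row[[paste0("sd_", l)]] <- stats::sd(x[g == l])
      }
      if (two) {
        tt <- pooled_t(x[g == lv[1]], x[g == lv[2]])
        row$t <- tt$statistic; row$df <- tt$df; row$p <- tt$p_value
      }
      cont <- rbind(cont, row)
    } else {
      tab <- table(x, g)
      res <- if (length(lv) >= 2) contingency_chi2(tab) else NULL
      catg[[v]] <- list(counts = tab, chi2 = res)
    }
  }
  list(groups = lv, continuous = cont, categorical = catg)
}

# Thresholds that reproduce the study's severity marginal distribution
# (counts 538/184/98/46/43/17 over categories 0..5+ in a sample of 926)
# on a standard-normal latent severity.
severity_thresholds <- function() {
  counts <- c(538, 184, 98, 46, 43, 17)
  stats::qnorm(cumsum(counts[-6]) / sum(counts))
}

#' Simulate the full set of study-style raw inputs
#'
#' Generates, from the 31-node ground-truth graph, every raw input the
#' pipeline consumes: an item battery measuring the 18 phenotype factors
#' (`items_per_factor` items each, loading `loading`), per-subject parcel
#' time series whose within-network coherence encodes the 12 network
#' connectivity nodes, and a truncated 0..5 severity count derived from
#' the latent severity node.
#'
#' @param seed master seed.
#' @param n number of subjects.
#' @param graph ground-truth graph (default [fig1_like_graph()]).
#' @param items_per_factor items measuring each phenotype factor.
#' @param loading item loading on its factor.
#' @param parcels_per_network parcels per network.
#' @param timepoints time series length per subject.
#' @return list with `battery`, `subject_runs`, `partition`, `severity`
#'   (integer counts), `truth` (the 31-column latent data and graph).
#' @export
simulate_study_inputs <- function(seed, n = 926, graph = fig1_like_graph(),
                                  items_per_factor = 5, loading = 0.7,
                                  parcels_per_network = 5,
                                  timepoints = 200) {
  latent <- simulate_linear_sem(graph, n, child_seed(seed, "latent"))
  factors <- latent[, factor_nodes(), drop = FALSE]
  networks <- latent[, network_nodes(), drop = FALSE]

  # battery: items load on their factor, unit total variance
  k <- ncol(factors)
  p_items <- k * items_per_factor
  set.seed(child_seed(seed, "battery"))
  E <- matrix(stats::rnorm(n * p_items, sd = sqrt(1 - loading^2)), n)
  L <- matrix(0, p_items, k)
  for (j in seq_len(k)) {
    L[((j - 1) * items_per_factor + 1):(j * items_per_factor), j] <- loading
  }
  battery <- scale(factors) %*% t(L) + E
  colnames(battery) <- paste0(rep(factor_nodes(), each = items_per_factor),
                              "_item", seq_len(items_per_factor))

  # parcel time series: subject's within-network target z is an affine
  # map of the network node value (center 0.55, slope 0.25)
  parcels <- paste0(rep(network_nodes(), each = parcels_per_network),
                    "_p", seq_len(parcels_per_network))
  partition <- stats::setNames(rep(network_nodes(),
                                   each = parcels_per_network), parcels)
  subject_runs <- lapply(seq_len(n), function(s) {
    z <- 0.55 + 0.25 * networks[s, ]
    # clamp so each 5-parcel block stays positive definite (r > -1/4)
    r <- pmin(pmax(tanh(z), -0.2), 0.95)
    sp <- timeseries_spec(partition, within_r = stats::setNames(r, network_nodes()),
                          between_r = 0, timepoints = timepoints)
    set.seed(child_seed(seed, paste0("ts_subject", s)))
    ts <- t(rmvnorm_chol(timepoints, sp$sigma))
    rownames(ts) <- parcels
    ts
  })
  names(subject_runs) <- sprintf("subj%04d", seq_len(n))

  severity <- simulate_symptom_counts(latent[, "aud_severity"],
                                      severity_thresholds())
  list(battery = battery, subject_runs = subject_runs,
       partition = partition, severity = severity,
       truth = list(graph = graph, data = latent))
}

#' Run the full discovery pipeline
#'
#' Stages, in order: exploratory factor analysis of the item battery
#' (parallel analysis to pick k, ML extraction, regression factor
#' scores); within-network connectivity summarization; assembly of the
#' factor-score + connectivity + severity matrix (all columns
#' standardized); GFCI causal discovery; SEM effect-size estimation on
#' the discovered graph; jackknife stability. Outputs are written under
#' `out_dir` with provenance headers (seed, config hash).
#'
#' @param config list with elements:
#'   \describe{
#'     \item{seed}{master seed (required).}
#'     \item{out_dir}{output directory (required).}
#'     \item{data}{optional precomputed subjects x variables matrix; if
#'       given, the EFA and connectivity stages are skipped.}
#'     \item{battery, subject_runs, partition, severity}{raw inputs (as
#'       from [simulate_study_inputs()]); alternatively `battery_file`,
#'       `timeseries_dir`, `partition_file`, `severity_file` paths.}
#'     \item{factor_scores}{optional precomputed scores matrix replacing
#'       the EFA stage.}
#'     \item{efa}{list(n_perm = 100, alpha_pa = 0.05, k = NULL).}
#'     \item{discovery}{arguments for [discovery_config()].}
#'     \item{stability}{list(fraction = 0.9, reps = 1000) or NULL to skip.}
#'     \item{stages}{character subset of c("efa", "connectivity",
#'       "discovery", "sem", "stability").}
#'   }
#' @return list with the stage results (`efa`, `scores`, `connectivity`,
#'   `matrix`, `pag`, `sem`, `stability`) and output paths.
#' @export
run_pipeline <- function(config) {
  nc_validate(!is.null(config$seed), "config$seed is required")
  nc_validate(!is.null(config$out_dir), "config$out_dir is required")
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(config$out_dir, "FAILED"))
  stages <- config$stages %||%
    c("efa", "connectivity", "discovery", "sem", "stability")
  prov <- c(paste("seed:", config$seed),
            paste("config_hash:",
                  config_hash(config[setdiff(names(config),
                                             c("battery", "subject_runs",
                                               "partition", "severity",
                                               "data", "factor_scores"))])))
  out <- list(provenance = prov)
  res_path <- function(f) file.path(config$out_dir, f)

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      writeLines(c(prov, paste("FAILED at stage:", name),
                   conditionMessage(e)),
                 res_path("FAILED"))
      nc_stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
              class = "neurocausal_pipeline_error")
    })
  }

  if (!is.null(config$data)) {
    mat <- as.matrix(config$data)
  } else {
    battery <- config$battery %||%
      (if (!is.null(config$battery_file)) read_data_matrix(config$battery_file))
    severity <- config$severity %||%
      (if (!is.null(config$severity_file))
        drop(read_data_matrix(config$severity_file)))
    scores <- config$factor_scores
    if (is.null(scores) && "efa" %in% stages) {
      run_stage("efa", {
        efa_cfg <- config$efa %||% list()
        pa <- parallel_analysis(battery,
                                n_perm = efa_cfg$n_perm %||% 100,
                                alpha_pa = efa_cfg$alpha_pa %||% 0.05,
                                seed = child_seed(config$seed, "parallel"))
        k <- efa_cfg$k %||% pa$k
        nc_validate(k >= 1, "parallel analysis selected 0 factors and no ",
                    "k override was given")
        model <- fit_efa(battery, k)
        scores <- factor_scores(model, battery)
        out$efa <- list(parallel = pa, model = model)
        write_data_matrix(scores, res_path("factor_scores.csv"), prov)
        utils::write.csv(model$loadings, res_path("efa_loadings.csv"))
        utils::write.csv(model$phi, res_path("efa_phi.csv"))
        utils::write.csv(
          data.frame(index = seq_along(pa$observed),
                     observed = pa$observed,
                     null_95 = pa$null_quantiles["95%", ],
                     p = pa$p_values),
          res_path("parallel_analysis.csv"), row.names = FALSE)
      })
    }
    conn <- config$connectivity
    if (is.null(conn) && "connectivity" %in% stages) {
      run_stage("connectivity", {
        runs <- config$subject_runs
        partition <- config$partition %||%
          (if (!is.null(config$partition_file))
            read_partition(config$partition_file))
        if (is.null(runs) && !is.null(config$timeseries_dir)) {
          files <- sort(list.files(config$timeseries_dir,
                                   full.names = TRUE))
          runs <- lapply(files, function(f) {
            m <- as.matrix(utils::read.csv(f, row.names = 1,
                                           comment.char = "#"))
            m
          })
          names(runs) <- basename(files)
        }
        conn <- connectivity_profiles(runs, partition,
                                       combine = config$combine %||% "mean")
        out$connectivity <- conn
        write_data_matrix(conn, res_path("connectivity.csv"), prov)
      })
    }
    parts <- list()
    if (!is.null(scores)) parts <- c(parts, list(scores))
    if (!is.null(conn)) parts <- c(parts, list(conn))
    mat <- do.call(cbind, parts)
    if (!is.null(severity)) {
      mat <- cbind(mat, aud_severity = as.numeric(severity))
    }
    out$scores <- scores
  }
  # standardize all columns so BIC penalties and SEM weights are on the
  # standardized scale
  mat <- scale(as.matrix(mat))
  attr(mat, "scaled:center") <- NULL
  attr(mat, "scaled:scale") <- NULL
  out$matrix <- mat
  write_data_matrix(mat, res_path("analysis_matrix.csv"), prov)

  dc <- do.call(discovery_config, config$discovery %||% list())
  if ("discovery" %in% stages) {
    run_stage("discovery", {
      out$pag <- gfci(mat, dc)
      write_pag(out$pag, res_path("pag.txt"))
    })
  }
  if ("sem" %in% stages && !is.null(out$pag)) {
    run_stage("sem", {
      spec <- pag_to_sem_spec(out$pag, on_cycle = "covariance")
      out$sem <- fit_sem(spec, mat)
      write_sem_result(out$sem, res_path("sem"), prov)
    })
  }
  if ("stability" %in% stages && !is.null(config$stability)) {
    run_stage("stability", {
      st <- config$stability
      out$stability <- jackknife(mat, dc,
                                  fraction = st$fraction %||% 0.9,
                                  reps = st$reps %||% 1000,
                                  seed = child_seed(config$seed, "jackknife"))
      write_stability_report(out$stability, res_path("stability.tsv"), prov)
    })
  }
  out
}
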