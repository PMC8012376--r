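# Benchmark scenarios with known causal ground truth.
#
# The three-variable motifs cover the canonical orientation cases (collider,
# common cause, chains); the hidden-confounder motif adds one anchor cause on
# each side of the confounded pair, because a latent common cause of an
# isolated pair is not identifiable from that pair alone, while the anchors
# make both arrowheads of the bidirected edge recoverable. The 31-node
# scenario mirrors the study design: 12 resting-state network nodes feeding
# a cognition -> social -> affective cascade terminating in a severity
# outcome whose sole direct cause is the externalizing node.

network_nodes <- function() {
  c("visual1", "visual2", "somatomotor", "cingulo_opercular",
    "dorsal_attention", "language", "frontoparietal", "auditory",
    "default_mode", "posterior_multimodal", "ventral_multimodal",
    "orbito_affective")
}

factor_nodes <- function() {
  c("somaticism", "fluid_cognition", "internalizing", "gambling_rt",
    "conscientiousness", "visuospatial", "social_support",
    "processing_speed", "externalizing", "social_withdrawal",
    "language_task", "relational_rt", "delay_discounting",
    "working_memory", "negative_affect", "crystallized_iq",
    "positive_affect", "agreeableness")
}

fig1_edges <- function() {
  e <- rbind(
    c("language", "default_mode", 0.5),
    c("language", "cingulo_opercular", 0.5),
    c("language", "posterior_multimodal", 0.4),
    c("language", "ventral_multimodal", 0.4),
    c("cingulo_opercular", "dorsal_attention", 0.4),
    c("cingulo_opercular", "frontoparietal", 0.4),
    c("posterior_multimodal", "dorsal_attention", 0.3),
    c("posterior_multimodal", "frontoparietal", 0.3),
    c("dorsal_attention", "frontoparietal", 0.3),
    c("frontoparietal", "fluid_cognition", 0.4),
    c("fluid_cognition", "visuospatial", 0.5),
    c("fluid_cognition", "crystallized_iq", 0.6),
    c("crystallized_iq", "working_memory", 0.5),
    c("crystallized_iq", "language_task", 0.5),
    c("crystallized_iq", "delay_discounting", 0.4),
    c("language_task", "agreeableness", 0.3),
    c("delay_discounting", "agreeableness", 0.3),
    c("working_memory", "social_support", 0.3),
    c("agreeableness", "social_support", 0.4),
    c("social_support", "negative_affect", -0.4),
    c("social_support", "social_withdrawal", -0.4),
    c("social_support", "positive_affect", 0.5),
    c("negative_affect", "internalizing", 0.5),
    c("negative_affect", "conscientiousness", -0.4),
    c("conscientiousness", "externalizing", -0.4),
    c("agreeableness", "externalizing", -0.4),
    c("externalizing", "aud_severity", 0.5)
  )
  data.frame(from = e[, 1], to = e[, 2], weight = as.numeric(e[, 3]))
}

# Choose noise variances so every variable has unit marginal variance and
# the edge weights are true standardized path coefficients.
standardize_noise <- function(nodes, edges, latent = character()) {
  g <- ground_truth_graph(nodes, edges, latent = latent)
  ord <- topological_order(g)
  nv <- stats::setNames(rep(1, length(nodes)), nodes)
  for (v in ord) {
    pa <- edges[edges$to == v, , drop = FALSE]
    if (!nrow(pa)) next
    g_tmp <- ground_truth_graph(nodes, edges, latent = latent, noise_var = nv)
    S <- implied_covariance(g_tmp, observed_only = FALSE)
    expl <- drop(t(pa$weight) %*% S[pa$from, pa$from, drop = FALSE] %*% pa$weight)
    nc_validate(expl < 0.99, "edge weights imply variance >= 1 at node ", v)
    nv[[v]] <- 1 - expl
  }
  ground_truth_graph(nodes, edges, latent = latent, noise_var = nv)
}

#' Study-scale ground-truth benchmark graph
#'
#' A 31-node linear-Gaussian DAG: 12 resting-state network connectivity
#' nodes feeding a cognition, social, and affective factor cascade that
#' terminates in an AUD-severity outcome caused directly (and only) by the
#' externalizing node. Standardized edge weights lie in 0.3-0.6; noise
#' variances are chosen so every variable has unit variance.
#'
#' @return a [ground_truth_graph()].
#' @export
fig1_like_graph <- function() {
  nodes <- c(network_nodes(), factor_nodes(), "aud_severity")
  standardize_noise(nodes, fig1_edges())
}

#' Generate the named benchmark suite
#'
#' Scenarios with known ground truth used throughout the test suite:
#' `collider` (X -> Z <- Y), `common_cause` (X <- Z -> Y), `chain_forward`
#' (X -> Z -> Y), `chain_backward` (Y -> Z -> X), `hidden_confounder`
#' (X <- L -> Y with L hidden plus observed anchor causes A -> X, B -> Y),
#' and `fig1_like` (see [fig1_like_graph()]).
#'
#' @param seed master seed; each scenario gets a child seed derived by
#'   stable hashing of its name, so the suite is reproducible and
#'   extensible.
#' @param n subjects per scenario (default 1000).
#' @return named list; each element has `graph` and `data`.
#' @export
make_benchmark_suite <- function(seed, n = 1000) {
  specs <- list(
    collider = standardize_noise(
      c("X", "Y", "Z"),
      data.frame(from = c("X", "Y"), to = c("Z", "Z"), weight = c(0.6, 0.6))),
    common_cause = standardize_noise(
      c("X", "Y", "Z"),
      data.frame(from = c("Z", "Z"), to = c("X", "Y"), weight = c(0.6, 0.6))),
    chain_forward = standardize_noise(
      c("X", "Y", "Z"),
      data.frame(from = c("X", "Z"), to = c("Z", "Y"), weight = c(0.6, 0.6))),
    chain_backward = standardize_noise(
      c("X", "Y", "Z"),
      data.frame(from = c("Y", "Z"), to = c("Z", "X"), weight = c(0.6, 0.6))),
    hidden_confounder = standardize_noise(
      c("A", "B", "X", "Y", "L"),
      data.frame(from = c("A", "B", "L", "L"),
                 to   = c("X", "Y", "X", "Y"),
                 weight = c(0.5, 0.5, 0.6, 0.6)),
      latent = "L"),
    fig1_like = fig1_like_graph()
  )
  out <- lapply(names(specs), function(nm) {
    g <- specs[[nm]]
    list(graph = g, data = simulate_linear_sem(g, n, child_seed(seed, nm)))
  })
  names(out) <- names(specs)
  out
}
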