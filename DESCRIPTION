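Package: neurocausal
Title: Causal Discovery Pipeline for Multimodal Neurobehavioral Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for data-driven causal modeling of a
    clinical outcome from multimodal phenotype and brain-connectivity data.
    Provides exploratory factor analysis with maximum-likelihood (EM)
    extraction, oblimin rotation and Monte-Carlo permutation parallel
    analysis; within-network resting-state connectivity summarization
    (Fisher-z averaged parcel correlations); Greedy Fast Causal Inference
    (GFCI) combining Fast Greedy Equivalence Search over a Gaussian BIC
    score with conditional-independence refinement to a partial ancestral
    graph; structural equation model estimation of standardized edge
    weights and fit indices (RMSEA, TLI); jackknife edge-stability
    analysis; and a synthetic-data module that generates every input with
    known ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
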