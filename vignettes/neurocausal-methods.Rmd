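---
title: "Methods: causal discovery for multimodal neurobehavioral data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: causal discovery for multimodal neurobehavioral data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurocausal)
```

# The model family

Everything in this package lives in the linear-Gaussian world. The
generative model behind the synthetic data, the likelihood behind the
BIC score, the Fisher-z independence test, and the SEM estimator all
assume that each variable is a linear function of its direct causes plus
independent Gaussian noise. This is a deliberate, matched set of
assumptions: a score-based search with a Gaussian likelihood and a
partial-correlation test are only coherent with each other under
linear-Gaussian data, so the synthetic generator produces exactly that.
AUD severity — in real data a truncated 0–5 symptom count — is carried
through the discovery stage as a continuous column, consistent with the
Gaussian score used to search over it; the generator exposes both the
continuous latent severity and its discretized form so the sensitivity
of that choice can be examined.

# Stage 1: factor analysis of the phenotype battery

A battery of roughly a hundred items is reduced to a small number of
correlated domains.

**Extraction.** Maximum likelihood on the item correlation matrix via
the EM algorithm, using the Woodbury identity so each iteration costs
O(p²k). Convergence is declared when the relative change in the ML
discrepancy F falls below 1e-12 (default cap 10⁴ iterations); the tight
tolerance matters because the identity *communality + uniqueness = 1*,
which holds exactly at the ML solution, is only reproduced numerically
when EM is run well past "looks converged". Uniquenesses are floored at
1e-3; hitting the floor flags a Heywood case in the result rather than
failing, which keeps small-sample synthetic fits alive.

**Rotation.** Oblique direct quartimin — oblimin with γ = 0 — by the
classical gradient-projection iteration. γ is fixed at 0 because that is
the standard default when "oblimin" is requested without qualification;
the criterion and projection code are self-contained, so other members
of the family could be added. Rotation acts inside the model subspace,
so χ², RMSEA and TLI are identical before and after rotation (this is a
tested invariant). Factor columns are ordered by explained common
variance and sign-normalized (largest loading positive) to make output
deterministic.

**Retention (parallel analysis).** The observed correlation-matrix
eigenvalues are compared, index by index, against eigenvalues of data
in which each column has been independently row-permuted. Permutation
preserves every marginal distribution while destroying all inter-item
dependence, so it is the natural null for "how big is the m-th
eigenvalue by chance". The per-index p-value is the plain fraction of
null eigenvalues at least as large as the observed one, and k is the
largest m such that indices 1..m all have p below α (default .05). A
random-normal reference null is also implemented (`null = "normal"`),
since eigenvalue tables in the literature report both; the permutation
null is the default used for selection. Under pure noise the first
eigenvalue's p-value is approximately uniform, so k = 0 with probability
about 1 − α — the type-I behavior the acceptance suite measures over 50
runs.

**Scores.** The scoring method is a genuinely open choice; regression
(Thurstone) scores `Z R⁻¹ Λ Φ` are the default because they are the
common default in the field's software, with Bartlett
weighted-least-squares scores behind `method = "bartlett"`. Score
columns are standardized before entering discovery.

**Variance accounting.** Factor j's contribution is
`diag(ΛᵀΛΦ)ⱼ` (pattern × structure), which sums *exactly* to the total
communality, so per-factor proportions of common variance and their
cumulative sum are internally consistent for oblique solutions.

# Stage 2: within-network connectivity

For one subject's parcel × time matrix and a parcel → network partition,
each network's summary is the mean of atanh(r) over all C(m, 2) distinct
parcel pairs in the network. `fisher_z` treats |r| ≥ 1 as a domain error
rather than clipping — a perfectly correlated parcel pair is a data
defect the user should see. Multiple runs are combined by averaging the
per-run z summaries (robust to per-run scale offsets); concatenating
runs in time before correlating is available behind
`combine = "concat"`, since either convention is defensible and the
choice is not dictated by anything upstream. Between-network
connectivity is intentionally not computed.

# Stage 3: GFCI

**Score phase (FGES).** Greedy equivalence search over CPDAGs with the
decomposable Gaussian BIC, written here as
`score(child | parents) = −n·log σ̂² − c·(|parents|+1)·log n`
with σ̂² the ML residual variance and c the penalty discount (default 2).
Any affine-equivalent convention would induce the same search; this one
is used consistently, and *score equivalence* — Markov-equivalent DAGs
receiving identical totals — is a tested contract. The forward phase
applies the best valid Insert operator (clique condition on
NAyx ∪ T and the semi-directed-path blocking condition) while any
improves the score; the backward phase applies best valid Deletes; after
every operator the graph is re-completed to a CPDAG by extending the
PDAG to a consistent DAG (Dor–Tarsi) and recomputing the equivalence
class (skeleton + v-structures + Meek closure). All candidate
enumeration is in lexicographic node order with first-found tie-breaks,
making the search deterministic — several tests and the jackknife rely
on that. On every 3-node benchmark and a sampled set of 4-node DAGs the
result equals the BIC-optimal class found by exhaustive enumeration over
all DAGs (25 at p = 3, 543 at p = 4).

**Refinement phase.** Each FGES adjacency is retested for conditional
independence (Fisher z: statistic √(n−|S|−3)·|atanh ρ̂|, ρ̂ the partial
correlation via inversion of the correlation submatrix) given subsets of
each endpoint's adjacency set, at increasing subset size up to
`ci_depth` (default unlimited — at 31 variables the adjacency sets stay
small). After a provisional collider orientation, remaining edges are
retested against subsets of the possible-d-sep sets, as the FCI
adjacency theory requires when latents may be present. Edges only ever
*leave* in this phase: discovered adjacencies are a subset of the FGES
adjacencies (tested invariant).

**Orientation.** All endpoint marks are reset to circles; unshielded
triples X–Z–Y are oriented as colliders X*→Z←*Y exactly when Z is
absent from the recorded separating set for (X, Y). Pairs that were
never tested (non-adjacent already after FGES) get a separating set by
search; if none is found the score-phase orientation of that triple is
used as a fallback. The final rule set is Zhang's complete FCI rules
minus the selection-bias rules R5–R7, which cannot fire when selection
bias is assumed absent — the package makes that assumption explicitly
and documents it rather than carrying dead code. R4 (discriminating
paths) and the tail rules R8–R10 are implemented with explicit path
searches; at this problem size the searches are exact.

**Detecting confounding needs anchors.** A latent common cause of an
*isolated* pair is not identifiable: two observed variables alone yield
`X o-o Y`. The hidden-confounder benchmark therefore gives X and Y one
observed cause each (A → X, B → Y); the two unshielded triples then
force arrowheads at both ends of the X–Y edge, and the PAG reports
`A o-> X <-> Y <-o B`. This is the designed, testable signature of
confounding.

# Stage 4: SEM effect sizes

The discovered PAG is translated edge-by-edge into a linear SEM:
`A --> B` and `A o-> B` become the regression B ← A (a circle read as a
tail, the interpretation that preserves the most causal content);
`A <-> B` and `A o-o B` become residual covariances (`o-o` edges can be
dropped instead via `drop_circle_circle`). Every rule application is
written to a translation log so the mapping is auditable. In finite
samples, inconsistent independence decisions can orient a genuine cycle
into the PAG; translation then fails loudly by default, or — in the
pipeline, where robustness matters more — deterministically demotes one
cycle edge (circle-marked first, then lexicographic) to a residual
covariance, logging the demotion.

Estimation is plain covariance ML: Σ(θ) = (I−B)⁻¹Ψ(I−B)⁻ᵀ with
log-parameterized residual variances, minimized by BFGS from OLS start
values; χ² = (n−1)·F at the optimum, standard errors from the inverse
observed information scaled by 2/(n−1), standardized weights from
model-implied standard deviations (so they are invariant to column
rescaling — a tested property). RMSEA uses the (n−1) convention
throughout; reference implementations differ between n and n−1, and at
n above a few hundred the difference is far below reporting precision.
The TLI baseline is the independence model with free variances, whose
χ² reduces to −(n−1)·log|R|. The mean structure is not modeled. A fixed
specification can be refitted to any data matrix with matching columns,
which is how a discovered model is checked against alternately derived
network data.

# Stage 5: jackknife stability

`floor(0.9·n)` rows are drawn without replacement, GFCI is rerun, and
per node pair two frequencies are tallied: adjacency (any edge) and
exact-mark (the modal edge string). Mark frequency can never exceed
adjacency frequency. Per-replicate seeds derive from the master seed by
replicate index, so the report is reproducible and independent of
execution order. The full default is 1000 replicates; tests use 100
(and the fraction-1.0 degenerate case, where every replicate must equal
the full-data graph exactly).

# The synthetic study

The generator's defaults are the study conditions, chosen once:

* **31-node benchmark graph**: 12 resting-state network nodes (the
  ventral-attention/language node acting as source hub feeding default
  mode, cingulo-opercular and multimodal nodes, converging on
  frontoparietal), 18 phenotype factors in a cognition → social →
  affect cascade, and a severity outcome whose sole direct cause is the
  externalizing node. Standardized weights lie in 0.3–0.6 — strong
  enough for non-flaky recovery at n ≈ 926, weak enough to be
  realistic for individual-differences data; noise variances are solved
  so every variable has exactly unit variance, making the weights true
  standardized path coefficients.
* **Sample sizes**: n = 926 for study-scale discovery, n = 933 for the
  factor battery, matching the phenotype and imaging sample sizes of
  the design being emulated.
* **Battery**: 5 items per factor at loading 0.7 (communality ≈ 0.5,
  typical of good questionnaire items); acceptance batteries use
  loadings 0.6–0.8 on disjoint blocks.
* **Time series**: 12 networks × 5 parcels, 200 timepoints per subject
  in the pipeline tests; each subject's within-network target z is
  0.55 + 0.25 × (network node value), i.e. an average coherence near
  the Fisher z of r ≈ 0.5 modulated by individual differences, clamped
  to keep each block covariance positive definite.
* **Severity thresholds**: quantile cuts on the standard-normal latent
  chosen to reproduce the marginal severity distribution
  538/184/98/46/43/17 over categories 0..5+ in 926 subjects.
* **Seeding**: one master seed fans out to per-scenario child seeds by a
  stable polynomial string hash of the scenario name, so adding a
  scenario never perturbs existing ones.

What the generator does **not** emulate — and what passing tests
therefore cannot certify about real data: temporal autocorrelation,
motion and physiological artifacts in fMRI (the i.i.d.-over-time signal
is sufficient for the connectivity *statistic*, not for preprocessing
questions); non-Gaussian, skewed or ordinal phenotype items; missing
data (the analysis assumes complete cases); age/gender adjustment of
instruments; and any violation of linearity or faithfulness. Real-data
orientation accuracy will be worse than the synthetic benchmarks
suggest; adjacency recovery and the confounding signature are the
better-calibrated claims.

# Numerical choices and degenerate inputs

* Correlation-based machinery refuses constant columns by name rather
  than emitting NaNs.
* `fisher_z` raises a domain error at |r| ≥ 1; no silent clipping
  anywhere.
* BIC residual variances are floored at 1e-12 before the log;
  collinear parent sets raise an error naming the offending set.
* The SEM objective returns a large finite penalty outside the
  positive-definite cone, keeping BFGS inside the feasible region;
  solutions with non-PD Ψ or Σ are flagged inadmissible, not hidden.
* Ties everywhere — operator choice, subset enumeration, node order —
  resolve lexicographically, so identical inputs give identical
  outputs byte for byte.

# Problem sizes in the shipped tests

The unit suite runs at n between 300 and 10⁴ on 2–31 variables in
seconds. The acceptance suite uses the study-scale conditions: ten
discovery runs at n = 926 on 31 nodes, a 90-item battery at n = 933,
50 null retention runs, and a 100-replicate jackknife — a few minutes
on one CPU. These sizes are the package's chosen benchmark conditions;
the same code paths run unchanged at the full 1000-replicate jackknife.

# Known limitations

* Cross-sectional linear-Gaussian discovery cannot find cycles or
  time-lagged effects, and bidirectional real-world couplings will
  appear as a single dominant direction or a confounded edge.
* The penalized score intentionally ignores weak edges; absence of an
  edge is weaker evidence than presence.
* The EFA stage assumes continuous items (Pearson correlations);
  polychoric correlations for coarse ordinal items are out of scope.
* FCI orientation at moderate n can produce locally inconsistent marks
  (hence the audited cycle-demotion path in the SEM translation);
  edge *presence* is considerably more stable than edge *direction*,
  which is exactly what the jackknife quantifies.
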