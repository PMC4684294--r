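---
title: "Finding silent players by network propagation: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Finding silent players by network propagation: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(netsilent)
```

## The model

Tumor cohorts produce two sparse binary matrices over a shared sample set:
mutation status M and differential-expression (DE) status D. The genes that
mediate the path from an upstream mutation to downstream dysregulation —
kinases, phosphatases, transcription factors — often appear in neither
matrix: they are "silent". The working hypothesis is that silence is a
property of the *gene*, not of its *network neighborhood*: a mediator sits
close, in the protein-interaction network, to mutated genes and to
dysregulated genes simultaneously, across many samples.

`netsilent` operationalizes this in three stages.

**1. Sample-specific propagation.** The weighted network is
Laplacian-normalized, $W' = \Delta^{-1/2} W \Delta^{-1/2}$, which keeps
$W'$ symmetric and bounds its spectrum in $[-1, 1]$ (so the iteration
below is a contraction for $\alpha < 1$). Each sample's binary prior
$Y$ — one row of M or D, restricted to network genes, zero elsewhere —
is smoothed by

$$F^{(t)} = \alpha W' F^{(t-1)} + (1-\alpha)\,Y, \qquad F^{(0)} = Y,$$

whose fixed point is $F = (1-\alpha)(I - \alpha W')^{-1} Y$. $\alpha$
trades prior fidelity against network smoothness: at $\alpha \to 0$ the
result is just $(1-\alpha) Y$; at large $\alpha$ signal travels farther.
Stacking the per-sample results row-wise gives the propagated matrices
$M_P$ and $D_P$ over the full network gene universe.

**2. Thirteen per-gene features.** Raw frequencies ($\mu_M$, $\mu_D$),
propagated means and variances ($\mu_{M_P}$, $\sigma^2_{M_P}$,
$\mu_{D_P}$, $\sigma^2_{D_P}$), the cross-source agreement measures
$\rho$ (Spearman) and $\delta$ (dot product), the per-sample
max-combination $\chi_{\max}, \chi_{\text{mean}}$ ("near either signal"),
the per-sample min-combination $\nu_{\max}, \nu_{\text{mean}}$ ("near both
signals" — the silent-player signature), and eigenvector centrality
$\gamma$ (included so the model can separate genuine co-proximity from
mere hubness).

**3. Logistic scoring with AIC step-down.** Unpenalized logistic
regression of training-set membership on the features, then greedy
backward elimination: refit with each single term removed, drop the one
whose removal most lowers AIC, stop when no removal lowers it. Scores are
the stepped-down model's fitted probabilities; training and scoring are
in-sample over the network gene universe. Genes outside the network have
no features and are dropped from training (their count is reported).

Candidate silent players are genes outside the training set whose
combined-model score reaches a threshold (default 0.2) while the
mutation-only and expression-only models (fit from
$\{\mu_M, \mu_{M_P}, \sigma^2_{M_P}\}$ and
$\{\mu_D, \mu_{D_P}, \sigma^2_{D_P}\}$ respectively, each with its own
step-down) stay below it. The cross-source features are by construction
available only to the combined model.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `alpha` | 0.8 | propagation smoothness, in (0, 1) |
| `tol` | 1e-6 | L2 stopping rule on successive propagation iterates |
| `max_iter` | 1000 | iteration cap (typical convergence at α = 0.8 is well under 100) |
| `threshold` | 0.2 | high-score cutoff for silent-player candidacy |
| `top_k_survival` | 25 | non-pathway genes screened by log-rank tests |
| `var_type` | `"sample"` | n−1 variance denominator (`"population"` available) |

The α default of 0.8 is the reference setting; `alpha_sweep()` re-runs the
full pipeline over a grid (reference grid 0.01–0.99) and in our synthetic
checks the causal-ranking AUC moves by well under 0.05 across
α ∈ {0.2, 0.5, 0.8} — conclusions should not hinge on α.

## Numerical choices

* **Fixed node order.** Gene symbols are the identity (case-sensitive, no
  alias mapping — harmonize identifiers upstream); node order is C-locale
  lexicographic so all vectors and files align reproducibly. Duplicate
  edges keep the maximum weight; self-loops are dropped; non-positive
  weights are rejected.
* **Isolated nodes.** A degree-zero node has a zero row in $W'$, so its
  propagated value settles at $(1-\alpha)Y$; this is handled, not an error.
* **Batched propagation.** All samples are iterated together as columns of
  one dense right-hand side; the update is linear, so this equals
  independent per-sample runs, with per-sample convergence tracked.
  Batched and solo runs may stop at slightly different iterates; both are
  within `tol` of the same fixed point.
* **Exact collinearity in the full model.** Because
  $\max(a,b)+\min(a,b)=a+b$ pointwise,
  $\chi_{\text{mean}} + \nu_{\text{mean}} = \mu_{M_P} + \mu_{D_P}$: the
  13-feature design matrix is rank-deficient by construction. The IRLS fit
  aliases one term (NA coefficient, zero contribution to scores, warned).
  AIC is computed as $2k - 2\ell$ with $k$ counting every *declared*
  coefficient including the intercept and aliased terms, so carrying a
  redundant feature always costs 2 AIC units and step-down removes it.
* **Step-down determinism.** AIC ties between removal candidates
  (difference < 1e-10) remove the candidate occurring later in the
  canonical feature order.
* **Separation.** With strongly separable labels the IRLS fit is flagged
  (`separation = TRUE`) and the last-iterate coefficients are used;
  scores remain usable as rankings.
* **Undefined Spearman.** A constant propagated column has zero rank
  variance; its ρ is set to 0 with a warning.
* **Eigenvector centrality** is computed by power iteration on $W + I$:
  the spectral shift leaves eigenvectors unchanged but makes the Perron
  eigenvalue strictly dominant, so the iteration also converges on
  bipartite graphs (plain $W$ oscillates there). Uniform start, L2
  normalization, tolerance 1e-10. In a disconnected network the dominant
  component carries the mass; other components get near-zero scores.
* **Silent-player threshold is not monotone.** Raising the threshold
  tightens the combined condition but *loosens* the two single-source
  conditions, so a gene can enter the list at a higher threshold (e.g.
  scores 0.35/0.25/0.10 qualify at 0.3 but not at 0.2). A threshold of
  1.0 always empties the list, since scores live in (0, 1).
* **Log-rank degeneracies.** A gene with an all-zero (or all-one) status
  column is reported as untestable rather than raising an error; samples
  without clinical records are dropped per test.

## What the synthetic cohorts emulate — and what they do not

`generate_network()` grows a preferential-attachment (scale-free) graph —
echoing PPI degree heterogeneity, which is what makes degree normalization
and the centrality feature meaningful — with edge reliabilities uniform on
(0.5, 1]. `generate_cohort()` plants `n_causal` causal genes, each sample
activates each causal module independently (probability `p_active`), and
an active module mutates / dysregulates each network neighbor of its
causal gene independently (`p_mut_near`, `p_de_near`), on top of
background rates (`q_mut`, `q_de`). The causal genes' own M and D columns
are forced to zero: they are silent by construction. Survival is
exponential, with the hazard multiplied by `hazard_ratio` in samples with
any active module, and administrative censoring at `censor_time`. The
reference conditions are 500 genes, 200 samples, 10 causal genes,
attachment 3, `p_active` 0.5, neighborhood rates 0.4, background 0.02
(mutation) and 0.05 (DE); baseline hazard 0.02/month with censoring at 60
months gives a realistic event mix at hazard ratio 3. Everything is
byte-reproducible from the config seed.

Two deliberate design points:

* **Causal genes are planted on nodes with at least `min_causal_degree`
  (default 5) interactions.** Mediator proteins are well-connected, and a
  module needs several interactors before the per-sample conjunction of
  nearby mutation and DE signals averages into a stable ν signal; with
  the floor at the bare realizability minimum of 2, the ν-based ranking
  of planted genes is visibly weaker.
* **`cohort_pathway()` emulates curated training labels.** Training
  directly on the planted causal genes teaches every model — including
  the single-source ones — the "zero raw frequency, high propagated
  signal" signature, because all positives are silent; real curated
  pathways are dominated by genes that *are* recurrently mutated or
  dysregulated. `cohort_pathway()` therefore samples a fraction (default
  0.6) of the module-neighbor genes plus unrelated background genes, and
  never includes the causal genes. Under these noisier labels the fit
  stays away from separation and integration-only high scorers — silent
  players — emerge.

What the generator does **not** imitate: real mutation spectra,
copy-number structure, expression platforms, pathway curation biases, or
identifier noise. Passing the synthetic checks demonstrates that the
machinery recovers planted network-conjunction signal under heterogeneous
degrees and background noise; it does not certify performance on any real
cohort, which depends on the quality of the network and of the binary
calls fed in.

## Problem sizes used by the test suite

The suite exercises exact oracles on small instances (50-node propagation
against a dense solve, 8×6 feature tables against a per-definition loop,
exhaustive hypergeometric enumeration for N ≤ 20, a 10,000-draw
permutation null for the log-rank test), behavioral statistics at moderate
size (200 replicate step-down runs at n = 500 for the noise-removal rate),
and the end-to-end claims on ten replicate cohorts at the reference
conditions above, with the α sweep on one of them. These sizes were chosen
so every distributional claim has enough replication to be stable while
the whole suite stays quick to run.

## Known limitations

* Gene identity is string equality; no alias resolution.
* Training and evaluation are in-sample, as in the headline analyses this
  package supports; no cross-validation variants are provided.
* The logistic model is unpenalized: with very strong signal it can hit
  separation (flagged), and with near-collinear features individual
  coefficients — though not the scores — should be interpreted with care.
* Propagation treats the network as static and undirected; no
  restart-on-subnetwork or directed variants.
* The hypergeometric enrichment treats the scored universe minus the
  training set as the population; with very small high-scoring sets the
  test is conservative.
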