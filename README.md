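# netsilent

Network-based integration of somatic-mutation and differential-expression
profiles to prioritize **silent players**: genes that are neither frequently
mutated nor differentially expressed in a tumor cohort, yet sit close — in
the protein–protein interaction (PPI) network — to both kinds of signal
across samples. Such genes (typically signaling mediators: kinases,
phosphatases, transcription factors) are invisible to frequency-based
analyses of either data type in isolation, but are exactly where mutation
signals upstream and dysregulation signals downstream meet.

The package is aimed at computational cancer biologists with a weighted PPI
edge list, binary per-sample mutation and differential-expression (DE)
calls, and a curated disease gene set to train against.

## Method

**Per-sample network propagation.** For a network G = (V, E, w) with weight
matrix W and diagonal degree matrix Δ, edge weights are Laplacian-normalized,
W′ = Δ^(−1/2) W Δ^(−1/2), which bounds the spectrum of W′ in [−1, 1]. Each
sample's binary mutation vector Y (and separately its DE vector) is diffused
by iterating

    F(t) = α W′ F(t−1) + (1 − α) Y,   F(0) = Y,

until ‖F(t) − F(t−1)‖₂ < 10⁻⁶; the iteration converges to
F = (1 − α)(I − α W′)⁻¹ Y. The default propagation parameter is α = 0.8.
Stacking rows gives propagated matrices M_P and D_P (samples × network
genes): each gene's column is its *propagated mutation / DE profile*.

**Thirteen-feature consolidation.** Per gene g over n samples: raw
frequencies μ_M, μ_D; propagated means and variances μ_MP, σ²_MP, μ_DP,
σ²_DP; Spearman correlation ρ and dot product δ between the two propagated
columns; the "either signal" features χ_max, χ_mean (per-sample
max{M_P, D_P}, aggregated by max/mean); the "both signals" features ν_max,
ν_mean (per-sample min{M_P, D_P}) — the silent-player signature; and
eigenvector centrality γ.

**Scoring.** Logistic regression of training gene-set membership on the
features, log(p/(1−p)) = β₀ + Σ βᵢ xᵢ, followed by greedy AIC step-down
(repeatedly remove the term whose removal most lowers AIC). The stepped-down
model's probabilistic output is the per-gene score. Genes scoring ≥ 0.2
under the combined model but below 0.2 under models fit with only
mutation-derived or only expression-derived features are reported as
candidate silent players. Downstream utilities: ROC/AUC, per-feature KS
comparisons, hypergeometric enrichment against an independent census, and
log-rank survival stratification of the top non-pathway genes.

A synthetic-cohort generator (scale-free network, planted never-mutated
never-DE causal genes whose neighborhoods carry the per-sample signal,
survival times tied to module activity) makes the whole pipeline testable
offline.

## Worked example

```r
library(netsilent)

cfg     <- sim_config(seed = 1)          # 500 genes, 200 samples, 10 planted causal genes
net     <- generate_network(cfg)
cohort  <- generate_cohort(cfg, net)
pathway <- cohort_pathway(cohort)        # curated-pathway-style training labels
run     <- run_pipeline(net, cohort$M, cohort$D, pathway, clinical = cohort$clinical)
print(run)
```

```
netsilent_run
  genes in network universe : 500
  alpha = 0.8, silent-player threshold = 0.2
  model AUC (pathway recovery):
    combined         0.8000  (4 features retained)
    mutation_only    0.7383  (1 features retained)
    expression_only  0.7802  (1 features retained)
  univariate AUC:
    mu_M             0.7383
    mu_MP            0.7371
    mu_D             0.7802
    mu_DP            0.7420
  silent players (score >= 0.2 in combined model only): 7
 gene combined_score mutation_only_score expression_only_score threshold
 G089      0.2314745          0.09392762             0.1691392       0.2
 G284      0.2191822          0.12909390             0.1286644       0.2
 G061      0.2121996          0.09392762             0.1691392       0.2
 ...
```

The combined model recovers the training pathway better than either
single-source model (AUC 0.80 vs 0.74/0.78), and seven genes clear the 0.2
score threshold *only* when mutation and DE signals are integrated — these
are the silent-player candidates. When the planted causal genes themselves
are used as labels (they are never mutated or DE'd, so their raw
frequencies are exactly zero), the stepped-down combined model still ranks
them essentially perfectly (AUC ≈ 1.0 across ten replicate cohorts), while
ranking by raw mutation frequency is uninformative (AUC ≈ 0.01).

The same workflow is available from the shell:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "netsilent", package = "netsilent"))')
$CLI simulate --out cohort/ --seed 1
$CLI run --network cohort/network.tsv --mutation cohort/mutations.tsv \
     --expression cohort/expression.tsv --pathway cohort/pathway.txt \
     --clinical cohort/clinical.tsv --out results/
```

Subcommands: `simulate`, `propagate`, `features`, `train`, `evaluate`,
`survival`, `sweep`, `run`, `plot`. Exit codes: 0 success, 2 input error,
3 convergence failure, 4 statistical degeneracy.

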