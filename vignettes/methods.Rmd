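---
title: "Methods: semisupervised driver-gene prediction with gatsage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: semisupervised driver-gene prediction with gatsage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gatsage)
```

## The model and its assumptions

`gatsage` treats driver-gene identification in one tumor type as
semisupervised binary node classification on a protein–protein
interaction (PPI) graph. The underlying biological assumptions are:

* driver alterations leave multiomic fingerprints — elevated mutation
  frequency and variant allele fraction, differential expression and
  expression outliers in a subset of patients, methylation shifts, and
  copy-number events;
* genes act through networks, so a gene's neighborhood carries signal: a
  mutated driver tends to dysregulate the expression of its interaction
  partners (captured explicitly by the bipartite features, and implicitly
  by message passing);
* most genes can be labeled neither driver nor clean negative; they
  should inform the learned representations without contributing noisy
  targets to the loss.

The classifier is one single-head graph-attention layer followed by two
GraphSAGE layers and a two-way softmax. Attention weights each edge
(`softmax` over each node's neighborhood, self-loop included so isolated
genes attend to themselves); GraphSAGE's concatenation of self and
mean-aggregated neighborhood keeps a node's own evidence separable from
its neighbors', which in noisy PPI graphs limits the damage of
false-positive edges. After three layers each gene sees its 3rd-order
neighborhood.

## Feature engine

The fixed 36-column schema (`feature_schema()`) partitions into 26
genomic, 3 transcriptomic, 1 epigenomic and 6 network features. Decisions
a user should be aware of:

* **Fold changes.** Expression fold change is `log2` of the
  pseudocount-protected ratio of tumor and normal means (ε = 1e−6);
  the methylation fold change is the plain protected ratio without a log.
  Genes unmeasured in either group are set to 0 exactly.
* **Outlier counting.** The Grubbs statistic is used *signed*, upper tail
  only: a tumor sample counts as an outlier for a gene only when its
  z-score exceeds `G_p(N)`; strongly under-expressed samples do not
  count. Mean and SD are taken over tumor samples only, since the
  patient-outlier matrix columns are tumor samples. Constant genes
  (zero SD) produce all-zero rows.
* **VAF aggregation.** The variant allele fraction is defined per record;
  it is aggregated to gene level by the mean over the gene's mutation
  records.
* **Base conversions** count SNV records only (single-base A/C/G/T ref
  and alt, ref ≠ alt) as totals over samples, in the fixed 12-class
  order C>A, C>T, C>G, A>T, A>C, A>G, G>C, G>A, G>T, T>A, T>G, T>C.
* **CNV rate.** Per-sample event counts are |GISTIC call|; the tumor
  event sum is multiplied by the normal sample count and divided by the
  normal event sum times the tumor sample count. A gene with zero normal
  events receives one pseudo-event so the rate stays finite.
* **Normalization.** "Different scales must be reconciled" is
  implemented as min–max scaling of each *feature* across genes to
  [0, 1]; constant features map to 0. The transform is idempotent.
* **Covariates.** The 11 mutational-heterogeneity covariates are consumed
  as a table (they come from upstream tooling, not recomputed here);
  genes missing from the table are imputed with per-covariate medians.
* **Centralities.** Degree and betweenness may come from a second,
  unscored network (`centrality_graph` argument); by default the single
  supplied PPI graph serves both roles. Betweenness is normalized by
  `(n−1)(n−2)/2` so it feeds min–max scaling on a bounded range.

## Labeling

Positives are the supplied catalogue. Five exclusion categories are
removed before negatives are called; four arrive as gene lists
(pathway membership and external driver catalogues), while
"expression-associated with a driver" is computed: |Spearman ρ| ≥ 0.8
(configurable) with any positive gene over tumor samples. Excluded
non-positives stay unlabeled. By default unlabeled genes take part in
message passing only; a `pseudolabels = TRUE` mode instead assigns them
seeded fair-coin targets in the loss. Random targets inject label noise,
which is why the passive mode is the default — both are provided because
either reading of "random pseudolabels in semisupervised learning" is
defensible.

## Training: tunable parameters

| parameter | default | notes |
|---|---|---|
| `gat_out` / `sage1_out` | 64 / 128 | layer widths; the head is fixed at 2 |
| `train_fraction` | 0.7 | stratified by label — the positive class is tiny (tens of genes), plain splits can starve the test set |
| `learning_rate` | 0.01 | Adam, full-graph batches |
| `epochs` | 200 | loss plateaus well before this on the bundled fixtures |
| `dropout` | 0.5 | between layers, training only (inverted scaling) |
| `weight_decay` | 5e−4 | L2 on weight matrices and the attention vector, not biases |
| `leaky_slope` | 0.2 | attention LeakyReLU |
| `string_score_threshold` | 0.9 | edges kept strictly above; 0–1000-scale files auto-detected |

These optimizer values are the customary defaults of the cited layer
architectures; nothing in the training data pins them, and moderate
changes mostly trade training time for nothing on the bundled fixtures.
The final GraphSAGE layer uses an identity activation before the softmax
(a ReLU there would clamp logits at zero and stall learning); the hidden
GraphSAGE layer uses ReLU and the attention layer ELU. Neighbor sampling
(`sample_size` in `sage_forward()`) exists for very large graphs but
defaults to full neighborhoods — gene graphs are small enough.

## Numerical choices

* Cross-entropy probabilities are clamped to [1e−7, 1−1e−7].
* Attention softmax subtracts the per-neighborhood maximum before
  exponentiation.
* PR curves group tied scores into one point, so average precision does
  not depend on tie order; precision of an empty prediction set is 1, and
  smoothed precision at recall grid points beyond the maximum achieved
  recall is 0 (the conservative convention).
* θ (proliferation activity) has the closed form `(S·S_mean)/(S·S)` — no
  intercept, matching its definition as a pure scaling coefficient; an
  all-zero sample yields θ = 0 with a warning.
* Core-gene selection ranks by number of significantly coexpressed
  partners, breaking ties by mean |ρ| and then lexicographically, making
  the top-20 deterministic.
* Wilcoxon tests use the exact distribution when both groups have ≤ 20
  samples and the normal approximation otherwise; the proliferation
  screen uses raw p-values at 0.05 (Benjamini–Hochberg can be applied by
  the caller to the returned table).
* All stochastic steps (initialization, dropout, splits, simulation)
  derive from a single seed; reruns are byte-identical.

## The synthetic generator

`simulate_bundle()` emulates the *shapes* of the real inputs: log-normal
expression, Beta methylation, Bernoulli mutation occurrence with
Poisson(100) depths and Binomial(depth, 0.3) alt reads, sparse integer
CNV calls, standard-normal covariates, a preferential-attachment PPI
graph, and a 160-gene proliferation module sharing one latent factor.
Planted drivers carry every signal at once: mutation rate 0.25 vs 0.02,
+1.5 log2 expression shift, +0.15 β methylation shift, CNV event rate
0.4 vs 0.05, and extra wiring to network hubs. The default cohort is
2000 genes × 200 tumor + 30 normal samples with 50 drivers.

What it does **not** emulate: mutational signatures and trinucleotide
context, clonal structure, gene length and coverage biases, correlated
pathway co-mutation, batch effects, or realistic PPI noise. Passing the
recovery tests therefore demonstrates that the implementation can learn a
planted multiomic + topological signal far above the prevalence baseline
(and learns nothing when no signal is planted) — not that it reaches any
particular accuracy on real cohorts.

## Problem sizes used by the test suite

Unit tests run on 300–500-gene simulations (60–100 tumor samples); the
layer oracles use ≤ 8-node graphs against dense brute-force
implementations; the recovery checks train the full default 2000-gene
bundle across three seeds plus one no-signal null; statistical
calibration uses 500-replicate Wilcoxon simulations; these sizes give
stable pass/fail behavior at desk scale.

## Known limitations

* Single-head attention only; no multi-head averaging.
* Full-graph training; no mini-batching (fine up to tens of thousands of
  nodes, the intended regime).
* Methylation input must already be gene-level β; probe-to-gene
  aggregation is out of scope.
* The 11 covariates are consumed, never recomputed from sequence.
* Real-data headline numbers depend on controlled-access cohorts and
  licensed catalogues; the package validates structure and statistics on
  synthetic data instead.
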