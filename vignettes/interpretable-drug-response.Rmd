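---
title: "Interpretable drug response prediction on drug-cell-gene graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interpretable drug response prediction on drug-cell-gene graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Large pharmacogenomic screens measure the concentration of a drug needed to
inhibit a cancer cell line (IC50) across many drug-cell pairs. Two questions
follow: can missing or future responses be predicted, and can the prediction
be traced back to genes in a way a biologist can interrogate? `gtdr`
addresses both with a single model: a heterogeneous graph connecting drugs,
cell lines and genes, processed by stacked multi-head graph-attention
("Graph Transformer") layers whose attention coefficients double as
interpretable drug-gene association scores.

## From raw tables to a graph

Four delimited-text inputs drive the pipeline:

* a drugs x cells IC50 matrix,
* a cells x genes expression matrix,
* drug structures as SMILES (or a precomputed fingerprint bit matrix),
* a two-column table of known drug-target interactions (DTIs).

**Response preprocessing.** IC50s are log10-transformed; per drug, values
outside the central 95% percentile band (linear-interpolation percentiles,
inclusive bounds) are discarded. Remaining values are z-scored per drug with
the sample standard deviation and binarized with a one-standard-deviation
margin: more than 1 sd below the drug mean is *sensitive* (label 1), more
than 1 sd above is *resistant* (label 0), and everything between is
*uncertain* and excluded from training and evaluation. The margin rule means
roughly a third of screened pairs receive labels on Gaussian-like data;
callers should expect sparse label matrices.

**Node features.** Each entity type gets a square RBF similarity matrix
`S_ij = exp(-||x_i - x_j||^2 / p)` with bandwidth equal to the feature count
`p`: drugs over 2048-bit circular (Morgan-type, ECFP) fingerprints, cells
over their expression profiles, genes over transposed expression. Entity-
specific linear layers project the three similarity blocks to a shared
hidden width and the rows are stacked drugs-then-cells-then-genes.

**Edges.** Three blocks tile a symmetric adjacency with zero diagonal
blocks. Drug-cell edges mark *sensitive* labeled pairs only (sensitivity is
the positive class throughout); a binary train/test mask is applied as a
Hadamard product before assembly, so held-out labels can never reach the
training graph — a property the test suite asserts bit-for-bit. Cell-gene
edges carry the positive part of per-gene z-scored expression, connecting a
cell to the genes it expresses above that gene's average (the z-score axis
is configurable; per-gene is the default because "above-average expression"
is only meaningful relative to a gene's own distribution). Drug-gene edges
carry known DTIs (weight 1) over a padding value for unknown pairs: 0
("zero" mode) treats unknown links as absent and predicts best; 0.5 ("soft"
mode) keeps a weak edge everywhere so attention can diffuse beyond the
annotation, and is the default for interpretability runs.

## The model

Each Graph Transformer block computes, per attention head, scaled
dot-product attention restricted to each node's in-neighborhood (with a
self-loop), plus a *root* term that passes the node's own features through a
separate linear map — the standard contract of the Graph Transformer layer.
Edge weights multiply the unnormalized attention, so a 0.5-padded drug-gene
edge contributes half the mass of a known one at equal scores. Heads are
concatenated and linearly mixed, followed by GraphNorm (feature-wise
normalization across the node axis with a learnable mean-scale), the
activation, and dropout (training mode only). Predictions for a drug-cell
pair concatenate the two final embeddings and pass through fully connected
layers ending in a sigmoid; training minimizes binary cross-entropy
(probabilities clamped at 1e-7) full-batch with Adam. Full-batch training is
appropriate because the whole graph fits comfortably in memory at the scales
this package targets.

The forward and backward passes are implemented directly in matrix algebra
(the O(N^2) attention inner loops in compiled code), and the backward pass
is verified against central finite differences in the test suite. All
randomness — initialization and dropout — is governed by a single integer
seed; identical configuration and seed reproduce the loss trace exactly.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `hidden_size` | 40 | shared embedding width (divisible by `n_heads`) |
| `n_gnn_layers` | 2 | stacked attention blocks; 2 hops reach drug-gene-cell paths |
| `n_heads` | 5 | attention heads per layer |
| `n_fc_layers` | 2 | head depth: 2*hidden -> hidden -> 1 |
| `dropout_rate` | 0.2 | per-unit dropout after each block |
| `learning_rate` | 0.01 | Adam step size |
| `weight_decay` | 3e-3 | L2 on weight matrices (not biases or norm gains) |
| `epochs` | 400 | full-batch epochs |

The defaults were chosen on development cohorts (seeds distinct from the
packaged evaluation seeds) as the smallest configuration that reliably
separates planted signal from memorization: dropout and weight decay matter
most, because the near-identity structure of RBF similarity rows otherwise
lets every entity memorize its training pairs through a private embedding
direction.

## Evaluation protocols

**Random masking (test1).** Labeled pairs are shuffled under a seed into
`k = 5` balanced folds; each fold in turn is zeroed out of the drug-cell
adjacency, the model retrains, and the held-out pairs are scored. Metrics
are AUROC (rank formula; ties credited 1/2 — equal to exhaustive
positive-negative pair counting) and AUPR (precision-recall step integral
over descending distinct thresholds). Per-fold values are aggregated by
unweighted mean and standard deviation.

**Leave-one-out cold start (test2).** Every drug (or cell line) with at
least 10 labeled entries and at least 2% of each class is held out in turn:
all its pairs are masked, the model retrains from scratch, and its pairs are
scored. This is the literal leave-one-out reading; a shared-training
approximation would be faster but would leak the target's edges and is
deliberately not offered as a default. Cold-start drugs keep only their
feature row (fingerprint similarity) and any visible DTI edges, so
performance measures how well structure carries mechanism.

## Attention interpretation

After training, one dropout-free forward pass captures per-layer, per-head
attention. Heads are averaged within each layer and layers summed, giving a
single node-by-node matrix; its drug x gene slice (by default the attention
drugs *receive from* gene neighbors; the transposed direction is a switch,
since either end of an edge can be read as the interpretandum) is ranked
per drug, ties broken lexicographically for determinism. Rankings feed:

* classification against the known DTI table (known vs novel, plus the
  fraction of known DTIs recovered),
* hypergeometric over-representation analysis of each drug's top-100 genes
  against GMT gene-set collections, Benjamini-Hochberg adjusted within each
  drug's family of sets (a global family is a flag; the per-drug family
  matches how one asks "what processes does *this* drug touch"),
* co-occurrence counting against an offline abstract index (the counting is
  in scope; live literature retrieval is not).

## The synthetic cohort generator

`generate_cohort()` produces fully self-contained cohorts with a planted
mechanism so the entire pipeline is testable without external data. Per
gene, expression is Gaussian with a gene-specific mean and scale; each drug
is assigned a *mechanism* (a set of target genes), and a cell's latent
sensitivity is the standardized expression of those targets times
`effect_size`. The continuous response is `log10(IC50) = -latent +
N(0, noise_sd)`, exponentiated so the standard preprocessing chain applies
unchanged. Mechanisms are shared: by default about five drugs per mechanism,
mirroring the large mechanism-of-action classes (kinase inhibitors,
DNA-damage agents, ...) that real screens contain — this redundancy is
exactly what masked-matrix evaluation is designed to exploit, and without it
no method can beat chance on held-out pairs because single-target drug rows
are statistically independent. Fingerprints overlay a per-mechanism random
bit signature (32 of 128 bits) on sparse background bits (rate 0.03), so
mechanism-mates are near-identical in fingerprint space while unrelated
drugs are clearly separated; a configurable fraction (default half) of the
planted drug-target pairs is exposed as the "known" DTI table.

What the generator does *not* emulate: cell-level general sensitivity
(pan-sensitive or pan-resistant lines), lineage clustering of cell lines,
correlated gene modules, and realistic IC50 marginals. Real screens contain
strong cell main effects that make masked-entry prediction substantially
easier; passing scores on synthetic cohorts therefore understate — and say
nothing quantitative about — performance on real data. Conversely the
planted ground truth enables recovery checks real data cannot support.

## Numerical choices and degenerate inputs

* Percentiles: linear interpolation (type 7), inclusive band edges.
* Standard deviations: sample convention (n-1) everywhere.
* Zero-variance drugs binarize to all-uncertain with a warning rather than
  erroring, so sparse real screens do not abort a run.
* Zero-variance genes get all-zero adjacency columns with a warning.
* Attention over an isolated node reduces to its self-loop (sums to 1).
* BCE probabilities clamped at 1e-7; GraphNorm variance floored at 1e-5.
* Ranking ties and gene orderings are broken lexicographically; drugs,
  cells and genes are sorted lexicographically at load, so every matrix and
  report has one canonical order.

## Problem sizes of the packaged evaluations

The packaged acceptance checks use cohorts of 40 drugs x 30 cells x 200
genes (270 graph nodes), one target gene per drug, effect size 2, noise sd
0.5, evaluated over three cohort seeds with 5-fold masking and
leave-one-drug-out runs pooled across cohorts to 20 held-out drugs — sizes
chosen so a complete evaluation runs in minutes on a single CPU while
leaving the planted-signal recovery comfortably measurable.

## Known limitations

* The concatenation-plus-MLP prediction head must *learn* the multiplicative
  drug-by-cell interaction; at a few hundred training pairs this is the
  binding constraint on cold-start performance, and held-out drugs whose
  DTI edges are absent (zero padding) lean entirely on fingerprint
  similarity.
* Attention coefficients are association scores, not causal claims; soft
  padding deliberately lets attention spread beyond annotated links, which
  raises recall of plausible associations at the cost of precision.
* Single-omics only: expression is the sole molecular layer.
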