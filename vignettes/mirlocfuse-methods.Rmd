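---
title: "Predicting miRNA subcellular localization from multi-source features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting miRNA subcellular localization from multi-source features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

MicroRNAs act in specific cellular compartments — silencing mRNAs in the
cytoplasm and processing bodies, binding regulatory elements in the nucleus,
travelling between cells in exosomes and microvesicles — so knowing where a
miRNA resides constrains what it can be doing. Experimental localization is
expensive, and a miRNA frequently occupies several compartments at once, so
the computational task is *multi-label*: each of `n` miRNAs carries a subset
of seven localizations (cytoplasm, exosome, nucleolus, nucleus,
extracellular vesicle, microvesicle, mitochondrion).

Sequence alone predicts localization only moderately well. This package
implements a classifier that fuses five heterogeneous sources of evidence
about each miRNA:

1. **Sequence** — a weighted miRNA similarity network from Smith–Waterman
   local alignment;
2. **Disease associations** — which diseases a miRNA is implicated in;
3. **Drug associations** — which drugs it responds to;
4. **mRNA associations** — which mRNAs it targets;
5. **Target co-localization** — where its target mRNAs live.

## Feature construction

### Similarity kernels

For any binary association profile matrix \(A\) (miRNAs in rows) the
Gaussian interaction profile (GIP) kernel is
\[
GM(i,j) = \exp\!\big(-\lambda \lVert A_i - A_j\rVert^2\big),\qquad
\lambda = n \Big/ \sum_k \lVert A_k \rVert^2 ,
\]
a similarity that adapts its bandwidth to the mean profile density.

Sequence similarity normalizes pairwise local-alignment scores,
\(SW(i,j) = sp(i,j)/\sqrt{sp(i,i)\,sp(j,j)}\), computed here with a
score-only Smith–Waterman (defaults: match +2, mismatch −1, linear gap −2;
configurable, and a precomputed score matrix is accepted). Because many
off-diagonal \(SW\) values are zero, zeros are backfilled with the GIP
kernel; the resulting matrix defines a complete weighted sequence network
\(N_S\) whose edge weights are the similarities.

Functional similarity follows the Wang construction: each disease sits in
an acyclic parent–child hierarchy; the contribution of an ancestor decays
by \(\Delta = 0.5\) per step (max over downward paths), a disease's
semantic value sums the contributions over its ancestor closure, pairwise
disease similarity is the shared-ancestor contribution ratio, and two
miRNAs' functional similarity best-match-averages the similarities of
their associated disease sets. Zeros are again GIP-backfilled. Binarizing
this matrix at a threshold `T` (strict inequality) gives the functional
network \(N_F\).

**Choice of `T` (default 0.65).** The binarization threshold is a free
parameter of the method. The default was set by a mechanism argument: the
graph attention auto-encoder below aggregates each node's neighborhood
with attention coefficients that are a softmax of *sigmoid-bounded*
logits, so the ratio between any two coefficients in a row is at most
\(e \approx 2.7\). On a dense graph (at `T = 0.5` typical fused
similarities put a third of all pairs above threshold) attention is
necessarily near-uniform over a hundred neighbors and one encoder pass
averages all representations towards the global mean — the refined
features collapse. A threshold that retains only the top few percent of
pairs (mean degree in the single digits) keeps neighborhood aggregation
meaningful. `T` remains configurable, and a small grid search over `T`
with `cross_validate()` is cheap if a dataset behaves differently.

### Network embeddings (node2vec)

Each network is embedded by biased second-order random walks fed to
skip-gram with negative sampling: 64 dimensions for \(N_S\) (walks biased
by edge weight), 128 for each bipartite association network (miRNAs plus
partners as nodes; miRNA rows are kept). Defaults are the node2vec
authors' common settings — \(p = q = 1\), 10 walks per node of length 80,
window 5, 5 epochs, 5 negative samples — since nothing in the problem
suggests a departure from them. Training is single-threaded and seeded, so
embeddings are bit-reproducible; this costs speed but makes every
downstream number exactly repeatable.

### Graph attention auto-encoder (GATE)

The three association embeddings are refined over \(N_F\). One encoder
layer computes
\(h_i = \sigma\big(\sum_j \alpha_{ij} W x_j\big)\) with
\(\alpha_{ij} = \mathrm{softmax}_j\,
\mathrm{sigmoid}(v_s^\top \sigma(Wx_i) + v_r^\top \sigma(Wx_j))\)
over the neighborhood including a self-loop; the decoder reuses the
encoder parameters in reverse (transposed weights, shared attention, final
layer linear so real-valued embeddings are reconstructable). The loss is
feature reconstruction \(\lVert X-\hat X\rVert_F^2\) plus
\(\lambda_s \sum_{(i,j)\in E} -\log\sigma(h_i^\top h_j)\), the structure
term that keeps adjacent nodes' codes aligned. Defaults: one 128→128
layer, \(\lambda_s = 1\), Adam with learning rate \(10^{-2}\) for 400
epochs (chosen so the reconstruction loss has visibly plateaued on
datasets of a few hundred miRNAs), sigmoid activations. Gradients are
fully analytic, including the paths through the attention coefficients,
and are verified against finite differences in the test suite.

### Co-localization ratios

For each miRNA with target set \(M(m)\), the fraction of targets annotated
to each of the four mRNA compartments (cytoplasm, exosome, nucleolus,
nucleus) gives four features in \([0,1]\). mRNAs multi-localize, so the
four ratios need not sum to 1. A miRNA without targets has no defined
ratio; the package returns the zero vector with a warning — "no evidence"
is the least informative value and keeps the pipeline total. mRNA label
columns outside the four retained compartments are dropped with a warning.

The five blocks concatenate to 64 + 128 + 128 + 128 + 4 = 452 features.

## Classifier

The five blocks are projected to one token each (default width 64),
scaled dot-product self-attention runs across the five tokens, and a
residual connection adds each token back to its attended value; the
concatenated output feeds two ReLU hidden layers (256, 64) and a 7-unit
sigmoid output trained with summed binary cross-entropy under full-batch
Adam (learning rate \(10^{-3}\), 300 epochs). The residual connection is
part of the standard attention block and matters here: without it the
row-stochastic mixing at initialization blurs all five token streams
together and the layer starts from a strictly less informative
representation than its input. Setting `use_attention = FALSE` removes
the layer entirely (the flat features feed the hidden layers directly),
which is also the ablation used to quantify the layer's contribution.

Scores become label sets via a threshold (default 0.5, with ties
predicted); evaluation uses the Chou-style set metrics — aiming,
coverage, accuracy, absolute true, absolute false — plus per-label
ROC/PR areas computed from out-of-fold scores pooled across a seeded
shuffled k-fold split (default k = 10), so each label has one curve.
An empty predicted set contributes 0 to aiming (the 0/0 case), a
conservative convention that penalizes abstention. AUC uses the rank
statistic with half credit for ties; AUPR integrates the
precision–recall step curve with tied scores grouped.

## Synthetic data

Real localization annotations (RNALocate), association databases (HMDD,
ncDR, miRTarBase) and miRBase sequences require downloads and identifier
reconciliation, so the package ships a generator that emulates their
joint structure with a planted, recoverable signal:

* each miRNA draws its 7-label vector from marginal prevalences
  (rejection-sampled to at least one label) whose default skew mirrors
  real data — the exosome-like label by far the most common, the
  nucleolus-like label the rarest;
* every disease, drug and mRNA carries a latent localization affinity
  (prevalence-weighted), and each association is drawn, with probability
  `s`, by first picking one of the miRNA's localizations and then a
  partner from that localization's pool — so partners of rare
  compartments stay represented — and uniformly otherwise; per-miRNA
  association counts scale with the number of localizations carried
  (multi-compartment miRNAs are the well-studied ones), so the
  strongly-associated half of the miRNAs also carries more labels, as in
  real data;
* mRNA 4-class labels are determined by the mRNA's affinity with
  probability `s`, background-sampled otherwise;
* the disease hierarchy is a branching tree (default branching 3) with
  occasional second parents, acyclic by construction;
* sequences are random RNA with a 6-mer motif per held localization
  planted with probability `s`.

The signal therefore lives *only* in the network structure and sequence
content; embedding, auto-encoding and the co-localization scheme must
genuinely extract it. At `s = 0` the features are independent of the
labels (a negative control verified by permutation tests); at `s = 1`
each miRNA's own-compartment co-localization ratio dominates in
expectation.

The canonical benchmark instance uses 300 miRNAs, 120 diseases, 40 drugs,
400 mRNAs, `s = 0.8`, mean association counts of 10/3/8 per miRNA
(diseases/drugs/mRNAs, roughly the per-miRNA density of the real
association tables scaled to these pool sizes) and seed 7. What the
generator does **not** emulate: identifier noise, annotation bias towards
well-studied miRNAs, correlated disease comorbidities, or sequence
families/paralogy — so passing tests on synthetic data demonstrate that
the pipeline recovers relational localization signal, not that real-data
accuracies will match.

## Numerical choices

* Similarity matrices are validated to be symmetric within \(10^{-9}\),
  with unit diagonal forced before downstream use (the functional
  similarity of a miRNA with an empty disease set would otherwise be 0).
* A pair of empty disease sets has functional similarity 0 off-diagonal;
  the best-match against an empty set is 0.
* Binarization uses strict `>`; a tie at exactly `T` yields no edge.
* Predictions are clipped to \([10^{-7}, 1-10^{-7}]\) inside the
  cross-entropy so the loss stays finite.
* All stochastic stages (walks, skip-gram, initializations, fold splits)
  draw their seeds deterministically from one master seed via stage-name
  hashing, so a full pipeline run is reproducible end to end and changing
  one stage's seed does not shift another's.
* Strongly/weakly group analysis ranks miRNAs by association count,
  breaking ties by input order; with an odd count the extra miRNA goes to
  the weakly group. The group boundary count is reported from the data
  rather than fixed.

## Problem sizes used in the shipped tests

The test suite and the acceptance script run the full pipeline on the
300-miRNA benchmark instance (10-fold cross-validation at the default
settings) and run the 31-subset feature ablation at reduced settings —
3 master seeds, 2 folds, 40 classifier epochs per subset — which keeps
the sweep's total cost near two hundred model fits while leaving the
size-group ordering stable across seeds. Formula-level checks use
hundreds of small random instances against independently coded
brute-force oracles.

## Known limitations

* The graph attention auto-encoder can *reduce* downstream accuracy when
  the raw embeddings are already clean, as on high-signal synthetic data:
  its bounded attention cannot concentrate on self beyond roughly a 2.7:1
  ratio, so every encoder pass partially averages a node with its
  functional neighbors. On noisy real-world embeddings such smoothing can
  denoise; on synthetic data with `s = 0.8` the raw embeddings are
  already clean and the no-GATE variant can outperform the full model. The `use_gate` switch makes the
  trade-off measurable per dataset.
* Runtime is dominated by cross-validation of the classifier (full-batch
  training in interpreted code); hundreds of miRNAs are comfortable, tens
  of thousands are not.
* The pipeline assumes all five sources exist for every miRNA; missing
  blocks are supported structurally (ablation mode) but there is no
  imputation.
* Identifier reconciliation across databases is the caller's
  responsibility; readers only guarantee consistency within one dataset
  directory.
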