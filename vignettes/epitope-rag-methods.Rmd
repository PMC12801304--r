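---
title: "Knowledge-graph retrieval-augmented epitope classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Knowledge-graph retrieval-augmented epitope classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(EpitopeRAG)
```

## The problem and the model

Short peptides (epitopes, 8-20 residues) presented by MHC molecules can
elicit interferon-gamma (IFN-gamma) secretion from T cells; predicting
which peptides do is a binary classification problem central to vaccine
and immunotherapy design. Purely sequence-based representations — even
per-residue embeddings from a pretrained protein language model — treat
every peptide in isolation and ignore the biological context a curated
reference collection carries: which molecule a peptide derives from,
which organism it originates from, which protein family (molecule
parent) it belongs to, and which host it was assayed in.

This package implements a retrieval-augmented pipeline that injects
that context into each query representation before classification:

1. **Embedding.** Every peptide is an $L \times D$ matrix of
   per-residue embeddings, standardized to $L = 20$ rows
   (zero-padded or truncated). The full-size setting is $D = 1280$
   from a pretrained transformer; the package is dimension-agnostic
   and ships a deterministic synthetic embedder for desk-scale work.
2. **Retrieval.** For a query $q$ the five reference epitopes with the
   smallest Euclidean distance
   $d_i = \sqrt{\sum_j (q_j - e_{ij})^2}$ (over the flattened matrix)
   are retrieved, never including an entry with the query's own id.
3. **Contextual weighting.** Each retrieved epitope starts with score
   $S_i = 1$. For every unordered pair and every shared property
   category — host, source molecule, source organism, molecule
   parent — the category's increment from a *relationship map* is
   added to both scores. Weights are the normalized scores
   $w_i = S_i / \sum_k S_k$; a neighbourhood with no queryable
   properties gets the uniform $w_i = 1/5 = 0.2$.
4. **Fusion.** The context embedding is the weighted average
   $W_{avg} = \sum_i w_i e_i$, and the fused representation is the
   convex combination $0.9\,q + 0.1\,W_{avg}$.
5. **Classification.** A multi-scale separable-convolution network
   (MSCNN) maps the fused $20 \times D$ input to a two-class softmax.

## The relationship maps

The increments encode how predictive a shared property is, with host
anchored at 1.0 and molecule parent least informative:

| category | human profile | mouse profile |
|---|---|---|
| host | 1.0 | 1.0 |
| source_molecule | 0.5 | 0.6 |
| source_organism | 0.6 | 0.5 |
| molecule_parent | 0.4 | 0.4 |

The profile is selected explicitly (`relationshipMap("human")`), never
auto-detected from the data. Property equality is exact string
equality after trimming surrounding whitespace; a category with either
value absent contributes nothing; each category counts at most once
per pair. The class label is stored on the epitope node but is
excluded from weighting unless `useLabel = TRUE` is passed explicitly
— sharing label information through retrieval would leak the target
into the representation.

A worked neighbourhood: if epitopes $E_1, E_2$ share host and source
molecule under the human map, both accumulate $1 + 1.0 + 0.5 = 2.5$
while $E_3..E_5$ stay at 1, giving weights
$(0.3125, 0.3125, 0.125, 0.125, 0.125)$:

```{r worked}
ps <- PeptideSet(paste0("e", 1:5), rep("ACDEFGHK", 5),
                 host = c("human", "human", "h3", "h4", "h5"),
                 source_molecule = c("gag", "gag", "m3", "m4", "m5"))
contextWeights(paste0("e", 1:5), buildKG(ps), relationshipMap("human"))
```

## The classifier

Each branch applies a *separable convolution*: a depthwise kernel of
width $w$ summing over the window within each input channel,
$\mathrm{Depthwise}(x)_{p,d} = \sum_{j} K_{j,d}\, x_{p+j-1,d}$,
followed by a pointwise $1 \times 1$ kernel mixing the $D$ channels
into $F$ filters (one bias per output filter). Convolutions are
unpadded ("valid"), so a window of width $w$ over 20 positions yields
$20 - w + 1$ outputs; branch outputs are max-pooled over all
positions, concatenated, passed through dropout, a hidden dense layer
and a softmax output. The human profile uses windows $\{2,4,6,8\}$;
the mouse profile drops window 8.

The trainable-parameter count has the closed form
$\sum_w (wD + DF + F) + (F B H + H) + (HC + C)$ with $B$ branches,
$H$ hidden units and $C$ classes. At full size
($D=1280$, $F=1024$, $H=500$, $C=2$) the blocks are 5,272,576 /
2,048,500 / 1,002, totalling 7,322,078 (~7.32M); the mouse window set
gives 5,488,094. `countParameters()` is verified in the tests against
the instantiated model's actual parameter count, and the depthwise
multiplier of 1 with a bias only on the pointwise output is what makes
the ~5.27M convolution block come out.

Training minimizes categorical cross-entropy plus an L2 penalty
$\lambda \sum w^2$ ($\lambda = 10^{-3}$) with Adam (learning rate
$10^{-3}$, moment decays 0.9/0.999, $\epsilon = 10^{-7}$), batch size
256, 20 epochs, dropout 0.7 — the full-size recipe. Design choices the
architecture description leaves open, fixed here:

* **Activations.** The separable-convolution equations and the layer
  table specify no nonlinearity; ReLU is applied after the pointwise
  convolution and after the hidden dense layer as the conventional
  default. Since ReLU is monotone, applying it before or after the
  positional max-pool is equivalent; the linear convolution op is what
  the loop-oracle test checks.
* **L2 placement.** On the two dense layers only, configurable to
  include convolution kernels (`l2OnConv`).
* **Dropout placement.** Once, after concatenation, before the hidden
  layer (inverted dropout).
* **Initialization.** Glorot-uniform kernels, zero biases, seeded from
  the config so training is reproducible on one machine.
* **Decision threshold.** 0.5 on the inducing-class probability.
* **No early stopping** — a fixed epoch budget.

The forward/backward passes are implemented directly with vectorized
matrix algebra (the heavy steps are BLAS matrix products) and the
gradients were verified against central finite differences during
development; the test suite pins the forward pass to an independent
nested-loop implementation.

## The synthetic data generator

`simulateEpitopes()` emulates, at desk scale, exactly the structure the
method exploits:

* a sequence signal: a short motif (default `"LP"` at the N-terminus)
  planted in inducing peptides with probability `motifStrength`
  (default 0.9) and never at that position in noninducing ones;
* a contextual signal: each class prefers its own pool of source
  molecules and organisms, mixed by `kgInformativeness` (default 0.8;
  0 makes metadata independent of class). Hosts are uniform and carry
  no signal; molecule parents group molecules pairwise;
* embeddings from the synthetic embedder plus Gaussian noise
  (`noiseScale`, default 0.5 — roughly half the unit scale of the
  per-letter base vectors, enough to keep single nearest neighbours
  imperfect without drowning the motif).

`simulateKnowledgeDB()` draws the reference set with the class
imbalance of a curated knowledge collection (169 inducing : 554
noninducing, scaled by rounding) and ids disjoint from any query set.

One subtlety worth naming: the synthetic embedder's per-letter table
plays the role of a pretrained model's frozen weights, so its seed
(`embedderSeed`) is deliberately decoupled from the per-dataset seed
and must be shared by every set that lives in one embedding space —
queries, held-out test and reference database. `runPipeline()` derives
it once from the master seed.

What the generator does *not* emulate: MHC-binding biology, realistic
embedding geometry (no evolutionary or physicochemical structure),
length-dependent class composition, or annotation noise in metadata.
Passing the end-to-end tests therefore demonstrates that the pipeline
recovers the kind of signal it assumes, not that it attains any
particular accuracy on curated immunology data — the full-size
numbers require external datasets and a pretrained embedder.

## Desk-scale problem sizes

The end-to-end checks use 1000 training and 400 held-out peptides at
dimension 32 with a 300-entry reference database, classifier scaled to
64 filters, 64 hidden units, windows per host profile, batch 64 and 30
epochs (regularization, learning rate and dropout keep their full-size
values; the smaller model needs more epochs than the full-size recipe
since the signal per parameter is lower). Under a strong planted
signal (`motifStrength = 1`, `kgInformativeness = 1`) held-out AUC
exceeds 0.95 and the KG-fused model is at least as good as the
query-only baseline on average across seeds; with all signal off,
held-out AUC is 0.5 within Monte-Carlo error (test n = 400 gives
sd(AUC) about 0.03 under the null).

## Numerical and format choices

* **Padding** is zero rows appended after the last residue
  (C-terminal); truncation keeps the N-terminal 20 rows. The
  convention is deterministic and documented rather than inferred.
* **Standardization acts on the embedding matrix**, not the sequence:
  no pad token is ever sent to an embedder.
* **Retrieval ties** break by ascending database index — a total
  order, so results are reproducible; the tests include exact-tie
  cases.
* **Distances flatten the matrix**; averaging and fusion are
  elementwise on matrices, preserving positional structure for the
  convolutional classifier.
* **The reference database stores raw standardized embeddings**;
  knowledge enters only through the weighting. Pre-fusing the
  database is a conceivable variant but couples database contents to
  one relationship map, so it is not the default.
* **Embedding containers** are plain TSV with 17 significant digits,
  which round-trips IEEE doubles bit-exactly.
* **Degenerate metric ratios** (zero denominators) report 0 with a
  warning; AUC uses the rank/Mann-Whitney estimator with half-credit
  ties, identical to the trapezoidal ROC area.
* **The knowledge graph is an in-process triple store** (node and edge
  tables) with TSV export/import: the weighting needs only four
  property lookups per epitope, and no external graph server can be a
  test dependency. Molecule parents resolve from the direct record
  attribute first, falling back to the
  Epitope→Molecule→MoleculeParent traversal; `IS_VARIANT_OF` edges
  are accepted on import but never weighted.

## Limitations

* The pretrained-embedder adapter is an interface (`embedFun`); the
  package does not bundle or download model weights, and all tests use
  the synthetic embedder.
* Retrieval is exact brute-force search — appropriate for reference
  sets of hundreds to thousands of entries, not millions.
* Relationship-map values are taken as given (tuned elsewhere); the
  package does not learn them.
* The classifier runs on CPU in plain R; full-size training (tens of
  thousands of samples at $D = 1280$) is out of its intended scale.
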