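# EpitopeRAG

Knowledge-graph retrieval-augmented classification of IFN-gamma-inducing
peptide epitopes.

## What it does and for whom

Peptides of 8–20 residues presented by MHC molecules can trigger
interferon-gamma (IFN-gamma) release from T cells; telling inducing
from noninducing peptides in silico matters for vaccine and
immunotherapy design. Sequence embeddings alone treat each peptide in
isolation. This package, aimed at computational immunologists and
method developers, enriches each query's per-residue embedding with
biological context retrieved from a curated reference set before
classifying it:

1. **Retrieve** — the 5 nearest reference epitopes by L2 distance
   `d_i = sqrt(sum_j (q_j - e_ij)^2)` over the flattened 20 × D
   embedding (self-matches by id are excluded).
2. **Weight** — each retrieved epitope starts at score S = 1.0; for
   every pair sharing a property (host, source molecule, source
   organism, molecule parent — looked up in a typed knowledge graph) a
   category-specific increment from a relationship map is added to
   both scores; weights are the normalized scores
   `w_i = S_i / sum(S)`. The human map is
   `{host: 1.0, source_molecule: 0.5, source_organism: 0.6,
   molecule_parent: 0.4}`; with no shared properties the weights fall
   back to the uniform 0.2.
3. **Fuse** — `0.9 * query + 0.1 * sum_i w_i e_i` (a 9:1 convex
   combination preserving the dominant sequence signal).
4. **Classify** — a multi-scale separable-convolution network
   (depthwise window kernels of widths {2,4,6,8} for the human
   profile, {2,4,6} for mouse, then 1 × 1 pointwise mixing into 1024
   filters, positional max-pooling, dropout 0.7, a 500-unit dense
   layer, 2-class softmax; 7,322,078 trainable parameters at full
   size). Evaluation covers sensitivity, specificity, accuracy, MCC,
   precision, F1 and rank-based AUC with ROC construction.

A deterministic synthetic embedder and a seeded data generator (planted
sequence motif + class-correlated metadata) let the whole pipeline run
and be tested at desk scale with no downloads; an adapter hook
(`embedFun`) accepts per-residue embeddings from any pretrained
protein language model.

## Worked example

```r
library(EpitopeRAG)

# contextual weighting, the core operation: e1/e2 share host + molecule
ps <- PeptideSet(paste0("e", 1:5), rep("ACDEFGHK", 5),
                 host = c("human", "human", "h3", "h4", "h5"),
                 source_molecule = c("gag", "gag", "m3", "m4", "m5"))
contextWeights(paste0("e", 1:5), buildKG(ps), relationshipMap("human"))
#> $weights
#> [1] 0.3125 0.3125 0.1250 0.1250 0.1250
#> $scores
#> [1] 2.5 2.5 1.0 1.0 1.0

# architecture accounting for the full-size human profile
countParameters(mscnnConfig("human"), byBlock = TRUE)
#> sepconv   dense  output   total
#> 5272576 2048500    1002 7322078

# end-to-end on simulated data with a strong planted signal
res <- runPipeline("demo_out", seed = 42, nTrain = 1000, nTest = 400,
                   nDb = 300, motifStrength = 1, kgInformativeness = 1,
                   verbose = FALSE)
round(res$metrics, 4)
#> sensitivity specificity    accuracy         mcc   precision          f1
#>      1.0000      0.9100      0.9550      0.9137      0.9174      0.9569
#>         auc
#>      0.9916
```

The weighting example shows both epitopes sharing host (+1.0) and
source molecule (+0.5) reaching score 2.5 and weight 0.3125 while the
unrelated three stay at 0.125. The pipeline run writes all artifacts
(peptide tables, embeddings, KG triples, fused embeddings, model
checkpoint, predictions, metrics, manifest) under `demo_out/`; the
held-out AUC of 0.99 reflects the strong synthetic signal, not
performance on curated immunology data.

A thin command-line wrapper with subcommands (`run`, `simulate`,
`embed`, `build-kg`, `fuse`, `evaluate`) is installed at
`inst/scripts/epitope-rag.R`.

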