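# slview

Multi-view graph convolutional prediction of **cell-specific synthetic
lethality** (SL) in R.

Two genes are synthetic lethal when a cell survives the loss of either
alone but dies when both are lost — the interaction behind PARP-inhibitor
therapy in BRCA-mutant tumours. Combinatorial CRISPRi screens measure SL
directly but only for hundreds of genes at a time, and SL relationships
are specific to a cell line, so population-level predictors transfer
poorly. `slview` is for computational biologists who have (or simulate) a
cell line's double-knockdown screen plus public network context and want
to prioritise unscreened pairs *in that line*.

## The model

Five views over one ordered gene universe of `N` genes — the cell-specific
SL graph (training positives only), physical and genetic
protein-interaction networks, and co-expression / co-essentiality networks
(Pearson correlation, exact-t two-sided `p < 0.01`) — are each normalized
as

```
Â_i = D̃_i^{-1/2} (A_i + I) D̃_i^{-1/2}
```

and encoded by a two-layer graph convolution with weights shared across
views:

```
Z_i = ReLU( Â_i · ReLU( Â_i X W0 ) · W1 ),   X ∈ R^{N×4}
```

where `X` holds per-gene expression, copy number, mutation and
essentiality. Element-wise max pooling fuses the five embeddings,
`Z_jk = max_i Z_i[j,k]`; a pair `(u,v)` becomes the symmetric feature
vector `[Z_u ⊙ Z_v, |Z_u − Z_v|]`; and a 64-32-16 feed-forward head emits
a probability of synthetic lethality, trained with binary cross-entropy,
Adam, per-epoch balanced negative resampling, and early stopping on a
validation holdout. Splits come in two modes: leave-gene-combination-out
(`"pair"`) and leave-gene-out (`"gene"`, novel genes at test time). Test
pairs are *forbidden*: an instrumented assertion fails any run in which a
test pair touches a gradient or an SL-view edge.

Backpropagation, Adam, and the ranking metrics (ROC-AUC, AUPR,
Precision@k%, F-max) are implemented in the package and pinned by
brute-force oracles in the test suite. A synthetic-data generator plants
a latent-factor SL signal with per-view informativeness so the whole
method runs with no downloads.

## Worked example

```r
library(slview)

ds  <- generate_dataset(synth_config(seed = 1))   # 300 genes, 1.5% SL pairs
cfg <- sl_config(seed = 1, learning_rate = 0.01,  # desk-scale recipe
                 max_epochs = 600, patience = 60)
fit <- fit_multiview_sl(ds, cfg)
fit
#> <sl_fit: pair split, views [SL, PPI_PHYS, PPI_GEN, COEXPR, COESS]>
#>   test: ROC-AUC 0.755 | AUPR 0.048 | Precision@5% 0.062 | F-max 0.103 (n = 8970)
#>   training: best epoch 50 of 110

glance(fit)      # one-row metric tibble
tidy(fit)        # per-epoch loss + validation monitor
autoplot(fit)    # training curves

# score arbitrary pairs (order-invariant by construction)
predict(fit, tibble::tibble(gene_a = "g0002", gene_b = "g0001"))
#> # A tibble: 1 x 3
#>   gene_a gene_b score
#>   <chr>  <chr>  <dbl>
#> 1 g0001  g0002  0.552

# ablation: random-graph baseline on the identical split
fit_rand <- fit_multiview_sl(ds, cfg, views = "RANDOM", split = fit$split)
fit_rand$metrics$roc_auc
#> [1] 0.639
```

The test ROC-AUC of 0.755 against 0.639 for the random-network baseline
is the synthetic analogue of the multi-view model's gain over a random
input graph; the positive class is 1.5% of pairs, so the AUPR baseline is
0.015.

A command-line front end wrapping the same functions lives at
`inst/cli/slview.R` (`simulate`, `build-graphs`, `train`, `predict`,
`evaluate`, each with `--config`, `--seed`, `--out-dir`).

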