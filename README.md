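# crisprattn

Attention-boosted deep models for CRISPR-Cas guide RNA design, with a
cell-specific network-based gene feature.

## The problem

Designing a good single-guide RNA (sgRNA) means balancing two risks. A guide
can cut where it should not (**off-target specificity**: will an imperfectly
matched genomic site with up to a handful of mismatches still be cleaved?),
and a guide can cut where it should but with unknown consequence for the cell
(**on-target efficiency and cellular response**: in a negative-selection
screen, how strongly does the guide deplete?). Sequence alone does not settle
the second question — the same guide targeting the same gene produces
different fitness responses in different cell lines, because the gene sits in
a different expression context.

`crisprattn` provides three trainable models for these tasks, plus the
cell-specific feature that links them to cellular context:

* **attn_to_mismatch** — off-target classifier. An aligned sgRNA–DNA pair of
  length *L* (20 nt Cas9 spacer, or 27 nt Cas12a window including the 4-base
  5' PAM) is tokenized position-by-position into one of 16 ordered base-pair
  types (sgRNA base × DNA base). Tokens are embedded, summed elementwise with
  a positional embedding, passed through multi-head self-attention encoder
  blocks (shape preserving), then two Conv2d + max-pool stages over the
  resulting *L* × *d* matrix, and a fully connected head with log-softmax over
  {active, inactive}.
* **attn_to_crispr** — on-target regressor. A guide sequence of length *L*
  is tokenized by a 2-base sliding window into *L* − 1 of 16 dimer types
  (indices from 0, 5'→3'), then the same embedding → transformer → CNN trunk,
  ending in a single linear output. Per-guide covariates (NetExpress, copy
  number) are concatenated before the fully connected layers.
* **seq_crispr** — on-target regressor with a CNN branch and an LSTM branch
  in parallel on the dimer embedding, flattened and concatenated (plus
  covariates) into the fully connected head.

The **NetExpress score** of gene *g* in cell line *c* is

```
NetExpress(g, c) = Σ_{j ∈ N(g)} w(g, j) · expr_c(j)
```

the sum over *g*'s neighbors in a weighted gene–gene interaction network
(STRING-style edge confidences *w*) of the neighbor's expression in that cell
line. It is the model's window onto cell-specific context: the same gene gets
a different score in every cell line.

Training follows the screening-data protocols: negative log-likelihood loss
with positive-oversampled balanced mini-batches for the heavily imbalanced
off-target task, mean squared error for regression, 5-fold CV /
leave-sgRNAs-out / leave-cell-line-out splitters, and AUC-ROC, PR-AUC,
Spearman/Pearson/MSE metrics. Feature attribution uses input-perturbation
importance: shuffle one feature column across samples, average the loss over
40 repeats, normalize across features to sum to 1.

All neural components (embeddings, multi-head attention, Conv2d/max-pool,
LSTM, Adam) are implemented in the package as a compact reverse-mode engine on
BLAS-backed matrix operations, verified against finite-difference gradients in
the test suite. Seeded synthetic-data generators plant recoverable signal
(position-weighted mismatch penalties; per-position dimer effects; a gene
effect transmitted through the network) so every claim is testable offline at
desk scale.

## Worked example

```r
library(crisprattn)

# synthetic off-target data: 4000 aligned pairs, mismatch penalties grow
# toward the PAM-proximal 3' end, top 20% by indel frequency labeled active
pairs <- gen_offtarget(offtarget_sim_config(seed = 11))
fit <- fit_offtarget_model(pairs, epochs = 10, seed = 11)
glance(fit)
#> # A tibble: 1 × 4
#>   auc_roc pr_auc n_folds     n
#>     <dbl>  <dbl>   <int> <int>
#> 1   1.000  0.998       1  4000
```

Held-out AUC-ROC ≈ 1.0 and PR-AUC ≈ 1.0: the classifier fully recovers the
planted position-weighted mismatch rule (a random scorer would sit at
AUC 0.5, PR-AUC ≈ 0.2, the positive prevalence).

```r
# on-target: 2500 guides in each of two cell lines; efficiency carries planted
# dimer effects plus a gene-level effect transmitted through the network
sim <- gen_ontarget(ontarget_sim_config(seed = 12))
fit2 <- fit_ontarget_model(sim$guides, network = sim$network,
                           expression = sim$expression, epochs = 12, seed = 12)
glance(fit2)
#> # A tibble: 1 × 5
#>     mse pearson spearman n_folds     n
#>   <dbl>   <dbl>    <dbl>   <int> <int>
#> 1  4.15   0.950    0.945       1  5000
```

Held-out Spearman ≈ 0.95 against a generative signal whose dimer term alone
cannot explain the cell-line differences — the NetExpress covariate carries
those. Dropping it (`use_netexpress = FALSE`) costs ~0.3 Spearman on this
benchmark, and `perturbation_importance()` ranks it as the top feature:

```r
tok <- token_matrix(encode_dimers(sim$guides))
rep <- perturbation_importance(fit2$model, tok[fit2$predictions$row, ],
                               sim$guides$efficiency[fit2$predictions$row],
                               extra = cbind(netexpress = sim$guides$netexpress,
                                             copy_number = sim$guides$copy_number)[
                                 fit2$predictions$row, ],
                               n_repeats = 40, seed = 12)
autoplot(rep)   # bar chart; normalized importances sum to 1
```

A thin command-line wrapper over the same functions lives at
`inst/cli/crisprattn.R` (subcommands `encode`, `netexpress`, `simulate`,
`run`), and `run_pipeline()` drives a full encode → train → evaluate →
importance run from a YAML config.

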