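---
title: "Models and methods in crisprattn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in crisprattn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(crisprattn)
```

This vignette is the package's own account of what it computes and why the
defaults are what they are. Nothing here states an empirical result that the
test suite or `scripts/acceptance.R` does not itself compute.

## Sequence tokenization

Two vocabularies, both of exactly 16 symbols:

* **Base-pair tokens** (off-target task): at each aligned position the ordered
  pair (sgRNA base, DNA base) is one of 4 × 4 types. A Cas9 spacer alignment
  of 20 nt yields 20 tokens; a Cas12a 27-nt window (which includes the 4-base
  5' PAM) yields 27.
* **Dimer tokens** (on-target task): a sliding window of length 2 over a
  single sequence, 5'→3', indices from 0; length *L* yields *L* − 1 tokens
  (19 for a 20-mer, 33 for a 34-mer).

The token ↔ symbol bijection is fixed lexicographically over
(A, C, G, T) × (A, C, G, T), so (A,A) = 0 … (T,T) = 15 (`token_vocab()`).
Internally one alphabet is used: RNA `U` maps to DNA `T` on ingest
(`canonicalize_seq()`), and ambiguity codes are rejected rather than imputed —
model inputs are fully resolved, ungapped sequences. Both choices are
conventions the data formats leave open; fixing them makes every encoding
byte-reproducible and round-trippable (`decode_base_pairs()`,
`decode_dimers()`), which the tests exercise exhaustively.

## NetExpress

For gene $g$ in cell line $c$, with network neighborhood $N(g)$ and edge
confidences $w$:

$$\mathrm{NetExpress}(g, c) = \sum_{j \in N(g)} w(g,j)\, \mathrm{expr}_c(j).$$

Exactly the one-hop weighted sum — no diffusion, no propagation, no implicit
normalization. Decisions around the edges of that definition:

* **Neighbors without expression values** contribute 0 (with a message); a
  strict mode errors instead. Network and expression gene universes rarely
  coincide in practice, so the permissive default is the usable one.
* **Confidence scale**: raw STRING combined scores (0–1000) are auto-detected
  on read (any value > 1) and divided by 1000; disable with
  `read_network(rescale = FALSE)`.
* **Expression transform**: values are used as provided; `read_expression()`
  offers `log2 = TRUE` (log2(x+1)) for count-like inputs.
* **Asking for a gene absent from the network is an error**, deliberately
  distinct from a present-but-isolated gene, which scores 0 (an empty sum).
* **Feeding into models**: extra features, NetExpress included, are z-scored
  with training-fold statistics before concatenation; the statistics are
  stored on the model and reapplied at prediction time. This keeps the
  covariate on a stable scale across folds without leaking test-set moments.

## Architectures

All three models share one representation: token embedding of width $d$
(default 32), for the attention models summed elementwise with a learned
positional embedding (a fixed sinusoidal table is available via
`positional = "sinusoidal"`).

* **attn_to_mismatch / attn_to_crispr**: the embedded $(L, d)$ matrix passes
  through `n_attention_layers` (default 2) post-norm transformer encoder
  blocks — multi-head scaled-dot-product self-attention (4 heads), residual,
  layer norm, position-wise feed-forward (width 64), residual, layer norm.
  Attention preserves the input shape, asserted at run time. The output is
  treated as a 1-channel image and passed through two Conv2d (3×3, 'same'
  padding) + ReLU + 2×2 max-pool stages with channels c(16, 32), flattened,
  optionally concatenated with extra features, and fed to fully connected
  layers c(128, 32) with dropout 0.2. The classifier head is a 2-unit
  log-softmax trained with negative log-likelihood; the regressor head is a
  single linear unit trained with mean squared error.
* **seq_crispr**: the dimer embedding feeds a CNN branch (as above) and a
  single-layer LSTM (hidden 32, final hidden state as branch output) in
  parallel; branch outputs are flattened and concatenated with extra features
  before the same fully connected head.
* **Decoder option**: the transformer in these models is encoder-only by
  default. With a single input stream there is no separate target sequence
  for a decoder to consume, so `use_decoder = TRUE` wires decoder-style
  blocks that self-attend the sequence and cross-attend the encoder output —
  available for fidelity to the two-part transformer, off by default.

The engine underneath is the package's own: reverse-mode layers (embedding,
positional, attention, layer norm, conv via cached im2col index tables,
max-pool, LSTM, dropout, linear) on plain BLAS matrix products, with Adam
(lr $10^{-3}$). Correctness is established by finite-difference gradient
checks over every architecture and by capacity tests (each model memorizes 64
random samples) in the test suite.

### Why these defaults

Embedding 32 / 2 blocks / 4 heads / fc c(128, 32) are the smallest settings
that saturate the planted-signal benchmarks below. Convolution channels are
c(16, 32): at these sequence lengths the wider alternative doubles CPU cost
without moving held-out metrics on any benchmark in the suite, and single-CPU
trainability is a design goal of the package. Adam at lr 1e-3 with early
stopping (validation fraction 0.1, patience 10 by default; the high-level
`fit_*` wrappers use patience 5) is a deliberately boring, robust optimizer
choice.

## Training protocols

* **Top-fraction labeling** (`label_top_fraction()`): exactly
  `round(fraction * n)` highest scores become positive, default fraction 0.2.
  Ties at the cutoff break by stable input order — arbitrary, but documented
  and deterministic.
* **Balanced mini-batches** (`balanced_batches()`): each batch draws half its
  slots from the negatives (every negative exactly once per epoch) and fills
  the other half with positives sampled with replacement, so positive
  fractions sit at 0.5 (0.4–0.6 tested). "Similar amounts" of each class is
  the intent; 50/50 is the concrete, testable reading. Evaluation never sees
  resampled data: metrics are computed on untouched held-out samples only.
* **Splitters**: `kfold_split()` (fold sizes differ by ≤ 1),
  `leave_groups_out()` for leave-sgRNAs-out and leave-cell-line-out, with
  train/test group disjointness asserted.
* **Metrics**: AUC-ROC by trapezoid over the tied-score ROC sweep (equals
  Mann–Whitney pair counting; cross-checked against pROC), PR-AUC as average
  precision over the same sweep (a random scorer's expected PR-AUC is the
  positive prevalence — the estimator has a small positive finite-sample
  bias, visible in the prevalence test's tolerance), Spearman/Pearson via
  `stats::cor`, MSE. Per-fold aggregation reports mean ± sd (`glance()`).

## Input-perturbation importance

For each input feature — one token position, or one named covariate — the
feature's column is permuted **across samples** (never within a sequence), the
loss (NLL or MSE, matching training) is computed on the perturbed data, and
the average over `n_repeats = 40` seeded permutations is the feature's raw
importance; raw scores are normalized by their sum. Two decisions worth
flagging:

* The raw score is the **post-shuffle loss itself**, not the increase over
  the baseline loss. Conventional permutation importance uses the delta; the
  post-shuffle loss preserves the same ranking (the baseline is a shared
  offset) and is what the normalization here operates on. The baseline loss
  is reported alongside (`attr(report, "baseline_loss")`).
* The shuffled unit is the **token**, not the underlying base. Overlapping
  dimers therefore become locally inconsistent with their neighbors after a
  shuffle; the models consume tokens, so this is the perturbation the model
  actually sees. Shuffling raw bases and re-extracting dimers would perturb
  two positions at once and blur per-position attribution.

Degenerate cases behave sensibly and are tested: with one sample the
permutation is the identity (uniform normalized scores); a feature whose
weights are provably zero scores exactly the baseline loss.

## Synthetic data: what it emulates, and what it does not

`gen_offtarget()` plants a position-weighted mismatch rule: decoys carry 0–6
substitutions at uniform positions (the at-most-6-mismatch convention for
candidate off-target sites); latent activity is
$100 \exp(-\sum_{p \in \text{mismatched}} w_p)$ plus Gaussian noise
(sd 5%), clamped to the 0–100% indel-frequency scale. Default weights grow
quadratically toward the 3' end, mimicking seed-proximal mismatch
intolerance. Defaults: 50 guides × 80 decoys = 4000 pairs, top 20% labeled
positive. Setting `label_fraction` to ~0.004 emulates the ~250:1 imbalance of
genome-wide mined negatives; the balanced-batch sampler is what makes that
regime trainable.

`gen_ontarget()` plants efficiency = per-(position, dimer) effects + a gene
effect transmitted through the network + noise. The gene term multiplies the
**standardized** NetExpress score (z across genes within a cell line), so the
coefficient is an effect size in SD units regardless of the expression scale;
the standardized value is returned as `netexpress_z` so tests can reconstruct
the formula exactly. A shared Erdős–Rényi network (confidences U(0.2, 1)) and
per-cell-line expression profiles give every guide two cell lines with
genuinely different efficiencies — cell specificity enters only through the
network-mediated term, which is what makes NetExpress informative exactly
when the planted coefficient is nonzero. Defaults: 2500 guides × 2 cell
lines, 34-nt sequences, 100 genes at density 0.05, noise sd 1.

What passing these benchmarks shows: the architectures can extract planted
positional/mismatch structure and a network-mediated covariate from data of
realistic shape and size. What it does not show: performance on real screens
— real indel-frequency noise is not Gaussian, real networks are scale-free
rather than Erdős–Rényi, real expression is far from independent across
genes, and real effect structure is not sparse-by-construction. Numbers on
the synthetic benchmarks are upper bounds on how cleanly signal can be
recovered, not predictions of performance on laboratory data.

## Problem sizes and numerical choices

The heavy checks in the test suite and acceptance script train at: off-target
n = 4000 (script: 2000), on-target n = 5000 (script: 2500), ablation
2 × 5 seeds (script: 3) × 800 records with a lighter configuration (embed 16,
1 block, channels c(8, 16)), importance on ~200 held-out samples with the
paper-default 40 repeats. These sizes are chosen so the full suite trains a
dozen models in a coffee break on one CPU while leaving wide margins over the
pass thresholds.

Other numerics: 'same' zero padding and stride 1 in convolutions with 2×2
floor max-pooling (odd trailing rows/columns are dropped); numerically stable
log-softmax and per-row max subtraction in attention; early stopping restores
the best-validation-loss weights; all randomness (initialization, batch
order, dropout, permutations, generators) flows through seeds, so every fit,
report and pipeline run is bit-reproducible single-threaded.

## Known limitations

* Training is CPU-bound and deliberately small; this is a desk-scale research
  implementation, not a production training system.
* The decoder wiring is one defensible reading of a two-part transformer over
  a single stream; others exist.
* The log2 fold-change normalization used for screen data is z-scoring within
  cell line — a documented choice where the convention is not fixed.
* `leave_groups_out()` draws holdout groups independently per seed; repeated
  draws can collide for tiny group universes.
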