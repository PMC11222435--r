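# sigmeth

Single-molecule 5-methylcytosine (5mC) calling at CpG sites from raw
nanopore current signal, for epigenomics work where bisulfite conversion
is impractical or per-molecule resolution matters. The package implements
the complete stack at desk scale, with a seeded squiggle simulator
standing in for the sequencer so that every stage is runnable and
testable on one CPU.

## What it does

* **Simulator** — k-mer current model with a methylation-induced level
  shift, per-base dwell and stride-based move tables, basecall errors with
  CIGAR-consistent alignments, CpG-island-structured references, and
  matched Bismark-style bisulfite coverage.
* **Feature extraction** — move-table and CIGAR bookkeeping that turns a
  read into per-CpG examples: an *l*-base token window centred on the
  assayed C, the window's signal blocks (*s* × *b* matrix), and
  window-relative reference/query indices.
* **Model** — a Pre-LN transformer encoder over signal blocks with hybrid
  positional encodings (absolute cosine/sine plus cosines of the relative
  reference and query indices), a decoder that cross-attends from the
  token window to the contextualized signal, and a linear modification
  head on the central cytosine:

  `Attention(K,Q,V) = softmax(Q Kᵀ / √d) V`,
  `MHA = [Attention₁, …, Attention_H] Wᴼ`,
  `P(5mC) = σ(w·h_center + b)`.

* **Training** — composite loss
  `L = L_mod + α (L_bases + L_signal + L_diversity)`: modification BCE,
  masked-base prediction, codebook signal classification (local targets,
  contextual predictions), and a diversity regulariser
  `log K + Σ p̄ᵢ log p̄ᵢ`; AdamW; fully seeded; hand-derived backprop
  verified by finite differences. Teacher→student knowledge distillation
  on soft labels.
* **Calling & aggregation** — per-read probabilities with no confidence
  filtering; strand-specific site records (coverage, methylated count,
  frequency).
* **Evaluation** — bisulfite-truth filters (max(P5, 5) coverage floor,
  partial-methylation band), confusion metrics and ranked-sweep average
  precision, genomic-context annotation (promoter/exon/intron/intergenic,
  repeats, island/shore/shelf, GC buckets, singletons), TSS-distance
  profiles, coverage CCDFs, confident-site comparison, and the
  high-filtering-position analysis.

## Worked example

Simulate a small dataset with a strong methylation shift, train a tiny
model end to end, call held-out reads and compare with the simulated
bisulfite truth:

```r
library(sigmeth)

pore <- build_pore_model(k = 2, mod_shift = 5, seed = 41,
                         level_sd = 0.25, dwell_mean = 9, stride = 5)
sim <- sim_config(ref_length = 10000, n_reads = 400,
                  read_length_mean = 1500, read_length_sd = 200,
                  truth_mix = c(0.5, 0.5, 0), bs_epsilon = 0, seed = 23)
res <- run_pipeline(
  sim, pore,
  fcfg = feature_config(l = 9, b = 5, mode = "reference"),
  mcfg = model_config(f = 64, H = 4, L_enc = 2, L_dec = 2, d_ff = 128,
                      b = 5, l = 9, K = 16, dropout = 0),
  tcfg = train_config(epochs = 2, batch_size = 64, lr = 2e-3,
                      alpha = 0.1, seed = 23),
  holdout_frac = 0.5)

res$read_metrics[, c("accuracy", "f1", "average_precision")]
res$site_metrics[, c("accuracy", "precision", "recall", "f1", "n")]
res$correlation
```

```
#> # A tibble: 1 × 3
#>   accuracy    f1 average_precision
#>      <dbl> <dbl>             <dbl>
#> 1        1     1                 1
#> # A tibble: 1 × 5
#>   accuracy precision recall    f1     n
#>      <dbl>     <dbl>  <dbl> <dbl> <int>
#> 1        1         1      1     1   365
#> $r
#> [1] 1
#> $n
#> [1] 349
```

Read-level accuracy is the fraction of held-out molecules whose
modification state is called correctly at probability threshold 0.5; the
site-level row compares aggregated methylation frequencies against
coverage- and partial-methylation-filtered bisulfite truth; `r` is the
Pearson correlation of paired site frequencies. At a level shift of 20×
the noise sd the problem is perfectly separable, so a correct
implementation reaches the values shown. `autoplot(res$model)` plots the
training-loss components; `tidy(res$model)` returns the per-step history.

A thin command-line interface over the same functions (subcommands
`simulate`, `extract`, `train`, `call`, `aggregate`, `evaluate`) is
installed at `inst/cli/sigmeth.R`.

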