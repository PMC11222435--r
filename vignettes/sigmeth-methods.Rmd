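---
title: "Calling 5-methylcytosine from nanopore signal: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling 5-methylcytosine from nanopore signal: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Nanopore sequencing reads the ionic current of a DNA molecule as it
translocates through a pore. A 5-methylcytosine (5mC) in CpG context
perturbs that current relative to unmodified cytosine, so the modification
can be called directly from the raw signal of a single molecule — without
bisulfite conversion and without the reference bias of short-read assays.
`sigmeth` implements a complete, desk-scale stack for this task: a seeded
squiggle simulator, feature extraction from basecaller move tables, an
encoder–decoder attention model over signal blocks and sequence tokens,
composite-loss training with self-supervised auxiliary tasks and knowledge
distillation, per-read calling with site-level aggregation, and a
benchmarking framework against bisulfite ground truth.

The expensive, irreproducible parts of the real workflow — basecalling,
FAST5/POD5 parsing, minimap2 alignment — are out of scope; their outputs
(basecalls, move tables, alignments) are consumed, not produced, and a
simulator stands in for the sequencer so that every stage is testable.

## Feature extraction

The basecaller emits, besides the sequence, a *move table*: one 0/1 entry
per fixed-stride signal step (stride $b$ raw samples; 5 for 4 kHz
super-accurate models, 6 for 5 kHz), with a 1 marking the start of a new
base. The cumulative sum of the moves therefore assigns every stride step
to a basecalled base (`signal_to_base_index()`). In reference-anchored mode
the CIGAR string extends this chain to reference coordinates
(`reference_query_mapping()`): aligned bases advance both coordinates,
inserted query bases carry the previous reference coordinate (flagged),
deletions advance the reference only, and soft clips are excluded.

For every CpG cytosine of the anchoring sequence whose window of $l = 31$
bases (package default; desk-scale runs use smaller odd $l$) fits inside
that sequence, `extract_examples()` emits one example: the token window
(always in read orientation, so the assayed C sits at position
$\lfloor l/2 \rfloor$ followed by G, and minus-strand sites are the reverse
complement of the forward genomic window), the $s \times b$ matrix of
signal blocks whose anchoring base falls in the window, and the
window-relative reference indices $r$ and query indices $q$ per block.
Windows overlapping read ends are dropped, not padded — the architecture
is fixed-length. Non-ACGT window bases map to an `[UNK]` token.

Two bookkeeping rules deserve mention:

* **Block-count filter.** Examples with fewer than $\lceil 0.5\,l \rceil$
  or more than $5\,l$ blocks are discarded and counted. The bound is
  interpreted *per window base*: the acceptable count is proportional to
  the window length, which matches plausible dwell ranges (one base dwells
  one to a few stride steps).
* **Relative query indices.** $q$ is made window-relative by subtracting
  the window's first query index and clipping to $[0, l-1]$; $r$ likewise
  from the window's start. Both are nondecreasing along the block axis.

Signals are normalized per read by median/MAD
($\tilde{x} = (x - \mathrm{med})/(1.4826\,\mathrm{MAD})$, falling back to
the standard deviation when the MAD is zero). Raw current scales drift
between reads and pores; a robust per-read affine normalization gives the
model a stable input scale without being distorted by signal spikes.

## Architecture

Signal blocks are projected to the latent space by
$\mathbf{S} = \mathbf{B}\mathbf{W}^S$ and given a hybrid positional
encoding $\mathbf{P}$. Reference-anchored (R9-style) models cycle four
encodings over the feature columns $j$:

$$
P_{ij} =
\begin{cases}
\cos(i \cdot \mathrm{pt}(j)) & j \bmod 4 = 0\\
\sin(i \cdot \mathrm{pt}(j)) & j \bmod 4 = 1\\
\cos(r_i \cdot \mathrm{pt}(j)) & j \bmod 4 = 2\\
\cos(q_i \cdot \mathrm{pt}(j)) & j \bmod 4 = 3
\end{cases}
\qquad \mathrm{pt}(j) = 10000^{-4\lfloor j/4 \rfloor / f}
$$

so absolute block position, reference index and query index all inform the
encoder. Basecall-anchored (R10-style) models use only the absolute
cosine/sine pair, with frequencies paired per two columns
($\mathrm{pt}(j) = 10000^{-2\lfloor j/2 \rfloor / f}$) to keep each
cosine/sine pair frequency-matched. The denominator of the positional term
is the full latent dimension $f$ (the standard sinusoidal convention); the
per-head dimension $d = f/H$ appears only inside attention.

The encoder is a Pre-LN transformer: each layer computes
$x \leftarrow x + \mathrm{MHA}(\mathrm{LN}(x))$ then
$x \leftarrow x + \mathrm{FFN}(\mathrm{LN}(x))$, with scaled dot-product
multi-head attention

$$
\mathrm{Attention}(K, Q, V) = \mathrm{softmax}\!\left(\frac{QK^\top}{\sqrt{d}}\right)V,
\qquad
\mathrm{MHA} = [\mathrm{Attention}_1, \ldots, \mathrm{Attention}_H]\,\mathbf{W}^O
$$

and a two-layer feed-forward network with a GELU nonlinearity. The token
window is embedded through a 6-row lookup table (four bases plus `[UNK]`
and `[MASK]`), given standard sinusoidal positional encodings, and decoded
by Pre-LN decoder layers that interleave self-attention, cross-attention
(queries from the sequence, keys/values from the contextualized signal)
and the feed-forward sublayer. Cross-attention is where signal-to-sequence
alignment is learned. The modification head is a linear map applied to the
contextualized representation of the central cytosine; its sigmoid is the
per-read, per-site modification probability. A configuration switch
(`use_decoder = FALSE`) bypasses the decoder for signal-only ablations, in
which case the head reads the mean-pooled encoder output.

Numerical choices: Pre-LN stacks carry *no* final layer norm, so
zero-layer stacks reduce exactly to their embedding paths (a property the
tests rely on); GELU uses the sigmoid approximation
$x\,\sigma(1.702x)$; layer norm uses $\varepsilon = 10^{-5}$; weights are
truncated-normal (sd 0.02), biases zero; argmax ties anywhere resolve to
the first index; dropout (default 0.1) acts after attention and
feed-forward sublayers during training only. The published base
(f = 384, 12+12 layers, 2048-d feed-forward) and small (f = 128, 6+6,
1024-d) presets are available in `model_config()`; all desk-scale work
here uses much smaller custom configurations.

## Training

The total loss is a linear combination

$$
\mathcal{L} = \mathcal{L}_{mod} + \alpha\,(\mathcal{L}_{bases} +
\mathcal{L}_{signal} + \mathcal{L}_{diversity})
$$

* $\mathcal{L}_{mod}$: binary cross-entropy of the modification logit
  against a hard or soft label (soft labels carry distillation).
* $\mathcal{L}_{bases}$: an independent fraction `p_mask` of window tokens
  is replaced by `[MASK]` and a disjoint `p_flip` fraction by a uniformly
  random base; cross-entropy of the 4-way base head at altered positions
  forces the model to read base identity out of the signal and to learn
  the local signal-to-sequence alignment.
* $\mathcal{L}_{signal}$: a codebook $C \in \mathbb{R}^{f \times K}$
  discretizes signal blocks. Targets are the argmax codeword of the
  softmax over codeword dot products with the *local* representation
  (block times $\mathbf{W}^S$, gradient-blocked); the chosen blocks and
  their $r, q$ entries are zeroed; predictions use the *contextualized*
  encoder representation. Computing targets locally and predictions
  contextually prevents the trivial identity solution.
* $\mathcal{L}_{diversity} = \log K + \sum_i \bar{p}_i \log \bar{p}_i$,
  with $\bar{p}$ the batch-average *soft* codeword assignment
  distribution: zero iff usage is uniform, at most $\log K$. The soft
  average is used because the hard assignment histogram has zero gradient;
  the hard histogram is still logged per step as a diagnostic.

Optimization is Adam with decoupled weight decay (learning rate
3e-4, weight decay 1e-4, $\beta_1 = 0.9$, $\beta_2 = 0.999$, no
schedule). Data order, masking, dropout and initialization all derive from
one seed; two runs with the same seed produce identical histories. The
auxiliary defaults `p_mask = 0.15`, `p_flip = 0.05`, `p_signal = 0.15`,
`K = 64`, `alpha = 0.1` are package choices (exposed in `train_config()`),
as the published account defers the numeric values to supplementary
material.

The backward pass is hand-derived (there is no automatic differentiation
here) and verified against central finite differences in the test suite;
a row-concatenated batched implementation makes training tractable on one
CPU and is asserted to agree with the per-example path.

Knowledge distillation (`distill()`) replaces labels with a trained
teacher's predicted probabilities, optionally mixing hard-labeled
examples; `sample_balanced()` reproduces the exactly-balanced stratified
sampling used to build distillation datasets, at whatever scale is asked
of it.

## The simulator

`simulate_reference()` generates a first-order Markov sequence whose CpG
dinucleotide rate is suppressed in the background and enriched (with
higher G+C) inside planted islands, then assigns every CpG site a truth
frequency from a three-class mixture (fully unmethylated, fully
methylated, partial). The two strand sites of one CpG share a frequency,
mirroring symmetric maintenance methylation. `simulate_read()` samples a
molecule: each CpG cytosine's state is Bernoulli in the truth frequency;
per-base dwell is a shifted geometric number of stride steps (minimum
one); the signal is Gaussian around the k-mer level, with `mod_shift`
added to every k-mer overlapping a methylated C so that the perturbation
spans a multi-base context and the decoder has something to align;
substitution and single-base indel errors corrupt the basecalled text (not
the signal — the molecule is what it is) and the CIGAR records them.
`simulate_wgbs()` draws per-site Poisson coverage and binomial methylated
counts with conversion error
$p = f(1-\varepsilon) + (1-f)\varepsilon$, in Bismark coverage dialect.

What the simulator does *not* emulate — and what passing tests therefore
do not establish about real data: pore-level kinetics (stalls, skips,
adapter signal), basecaller-correlated error profiles, k-mer-dependent
dwell, absolute current calibration (everything is in normalized units),
and sequence-context-dependent modification shifts beyond the additive
level model. Results on simulation demonstrate that the machinery is
correct and that the model class can extract a signal-level difference; they
are not evidence of accuracy on real flow-cell data.

## Calling and evaluation

`call_reads()` emits one probability per extracted example with no
confidence filtering — deliberately: downstream coverage is not silently
eroded, and the filtering-bias analysis below exists precisely to measure
what filtering costs other tools. `aggregate_sites()` groups calls by
(contig, position, strand) — strand-specific, single-base resolution —
and counts calls with probability strictly above 0.5 as methylated (a call
at exactly 0.5 counts unmethylated, a deterministic tie-break).

The evaluation framework mirrors standard bisulfite-truth practice:

* **Truth filtering** (`filter_truth()`): classification truth drops sites
  with coverage below $\max(P_5, 5)$ (nearest-rank percentiles throughout,
  for determinism) and partially methylated sites (frequency strictly
  inside $(0.01, 0.99)$); correlation truth keeps partials and adds a
  $P_{95}$ upper coverage bound.
* **Metrics** (`confusion_metrics()`): accuracy, precision, recall, FPR,
  F1, and average precision as the ranked sweep
  $\sum_k (R_k - R_{k-1}) P_k$, which is threshold-free.
* **Contexts** (`annotate_contexts()`): genic labels with precedence
  promoter > exon > intron > intergenic (promoter = TSS ± 2000 bp; introns
  are genes minus exons); repeat classes with priority SINE > LINE > LTR >
  DNA > Other (the boundary rule for overlaps is a package choice, as is
  mapping the 5-base-window G+C fraction to the smallest bucket of
  20/40/60/80/100% at or above it); CpG islands with 2 kb shores and the
  next 2 kb as shelves, island over shore over shelf; singletons are CpGs
  with no other CpG within ±10 bp.
* **TSS profiles** (`tss_profile()`):
  $\mathrm{bin} = \lfloor(\mathrm{pos} - P + \lfloor B/2 \rfloor)/B\rfloor$
  with $B = 50$ (125 for CTCF-style anchors); minus-strand offsets are
  negated first so upstream is consistently negative; per-tool coverage
  filters (ONT ≥ 3, bisulfite ≥ 5) and no cross-tool intersection.
* **Coverage CCDF** (`coverage_ccdf()`):
  $\mathrm{ccdf}(c) = N_{\geq c}/N_{\mathrm{sites}}$, with the companion
  strand-specific sequencing coverage $n_{\mathrm{bases}}/(2G)$.
* **Confident-site comparison** (`confident_site_comparison()`): a site is
  positive at coverage ≥ 5 and frequency > 50%, negative at coverage ≥ 5
  and frequency ≤ 50%, uncalled below 5×; categories are concordant,
  discordant-with-support, and unique (other method uncalled).
* **Filtering-bias analysis** (`high_filtering_analysis()`): positions are
  missing-low-overall (overall coverage < 5), missing-due-to-filtering
  (valid < 5 ≤ overall), high-filtering (valid ≥ 5 but filtered calls
  exceed 10% of overall), or ok.

## Desk-scale experiment design

The published models train on $10^8$-example datasets with GPU clusters;
nothing at that scale is reproducible on a laptop, so the package's
experiments are designed to exercise every mechanism at sizes where a CPU
suffices, and the test suite asserts behavior under those conditions:

* **Generator**: a 2-mer pore model (16 levels — small enough that the
  masked-base task is learnable in minutes, large enough that base
  identity requires combining adjacent blocks), per-sample noise sd 0.25,
  methylation shift 0.5 (twice the noise sd) for the recovery experiment
  and 5.0 (twenty times) for separability and pipeline-closure checks,
  ~9 samples per base at stride 5, ~20 kb references, ~2 kb reads.
* **Model**: 2+2 layers, $f = 64$, $H = 4$, $d_{ff} = 128$, $K = 16$,
  window $l = 9$, dropout 0 (at these model sizes and data volumes
  regularization only slows convergence).
* **Training**: 20 000 examples, 7 epochs, batch 64, learning rate 2e-3
  (small transformers tolerate and need a larger step than the
  full-scale 3e-4 default, which remains the package default),
  `alpha = 1` so the auxiliary tasks receive useful gradient at this
  scale. The null control (shift 0) trains a single epoch: one epoch of
  the same recipe with signal already reaches high accuracy, so
  chance-level accuracy after one epoch without signal is the informative
  comparison.
* **Distillation**: a 1+1-layer, $f = 32$ student on 10 000 soft-labeled
  examples, 3 epochs, `alpha = 0` (pure soft-target BCE; the teacher's
  probabilities are used directly, no temperature).
* **Pipeline closure**: 400 reads over 10 kb, no partial methylation, no
  bisulfite conversion error, shift 20× noise — conditions under which a
  correct implementation must reach F1 = 1 and near-unit correlation.

## Known limitations

* Pure-R training: practical up to tens of thousands of examples and
  $f \approx 128$; the full-scale presets are architectural documentation,
  not a training recipe.
* The simulator's additive, context-independent modification shift is a
  favourable caricature; transfer to real signal is untested here.
* Basecall-anchored mode reports read-local coordinates when no alignment
  is present; genomic aggregation then requires aligned inputs.
* BAM/CRAM, bedMethyl/modBAM and GFF3 are not parsed; gene tracks are
  consumed as BED, bisulfite truth as Bismark coverage text, reads as
  JSON-lines or SAM text with an `mv` tag.
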