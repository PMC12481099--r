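---
title: "Methods: efficient protein language model inference, scoring and fine-tuning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: efficient protein language model inference, scoring and fine-tuning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protlm)
```

## The model

`protlm` implements an ESM-style masked protein language model as explicit
matrix algebra. A sequence of amino acids is tokenized over the 33-token ESM
alphabet (`<cls>`, residue tokens, `<eos>`; rare codes map to their own
tokens, unknown letters to `<unk>`), embedded, passed through `num_layers`
transformer blocks, and projected to per-token logits over the vocabulary by
the LM head. Self-attention in each block is

$$\mathrm{Attn}(x)_i = \sum_j \mathrm{softmax}_j\!\left(\frac{q_i \cdot k_j}{\sqrt{d_h}}\right) v_j,$$

with $d_h$ the *per-head* dimension (not the embedding width). Two block
families are supported: GeLU feed-forward with post-layer-norm (the
ESM-1b/ESM-1v/ESM2 convention) and SwiGLU with pre-layer-norm (the ESM-C
convention). Positions are encoded either by a learned table — indexed with
a 2-row offset, the ESM-1x convention, so a table for $P$ positions has
$P + 2$ rows — or by rotary embeddings applied to queries and keys, whose
dot products depend only on relative offsets (a property the test suite
checks numerically rather than assumes).

All computation is in R doubles. The contracts written into the tests
(packed-vs-padded agreement to 1e-4, merge agreement to 1e-5, oracle
agreement to 1e-6) are the tolerances a 32-bit implementation would need;
in double precision the observed discrepancies are at machine epsilon, so
the same contracts hold with a wide margin.

## Sequence packing and token-count batching

The efficiency mechanism at the core of the package is *sequence packing*:
variable-length sequences are concatenated into one flat token stream with
boundary bookkeeping (`pack()`), and attention is restricted to
within-sequence pairs by the block-diagonal mask (`block_diagonal_mask()`).
Positions restart at zero at every boundary, so each protein sees its own
coordinates. Packing removes padding entirely; a batch's cost is its token
count, which is why the dataloader (`plan_token_batches()`) fills batches to
a *token* budget rather than a sequence count: sequences are sorted longest
first, placed greedy-first-fit under the budget, and batch order is then
shuffled with a seed. The heuristic is deterministic and reaches >50%
utilization (tokens per batch over budget) on a realistic length
distribution at a 16,384-token budget; the first-fit pass typically packs
all but the final ragged batch nearly full. An oversized single sequence
gets a singleton batch and is flagged in the returned report rather than
rejected.

The dense block-diagonal mask is the *reference semantics*. Internally the
forward pass evaluates attention block by block, which is arithmetic-
identical to masking a dense score matrix with $-\infty$ entries and has
the useful side effect that one sequence's computation cannot touch
another's — the no-leakage test asserts this bitwise. The central
equivalence oracle — packed forward equals per-sequence forward — is
exercised over random batches in both positional modes.

## Scoring

**Pseudo-perplexity.** Each residue position $t$ of a $T$-residue sequence
is masked in turn and the model predicts it from the full remaining
context:

$$\mathrm{PPL}(x) = \exp\!\left(\frac{1}{T}\sum_{t=1}^{T} -\log p(x_t \mid x_{\setminus t})\right).$$

Special tokens are never masked and never enter the average — "each
position" is read as *residue* positions, which keeps the statistic
comparable across sequences. The $T$ masked copies are evaluated through
the packing machinery itself (not a padded batch), so scoring exercises the
same code path as inference; the result is invariant to the batch plan. A
uniform-logit model scores exactly the vocabulary size (33), a perfect
model scores 1. Log-sum-exp is used throughout, so zero predicted
probabilities cannot produce infinities.

**Masked-marginal variant score.** For a substitution at position $p$, the
position is masked, the model is run once, and

$$v = \log p_\mathrm{alt} - \log p_\mathrm{ref}$$

is read off the masked position's log-softmax, in nats (the TSV header says
so). The reference residue is checked against the sequence and mismatches
fail loudly with the position and observed residue. Long proteins that
exceed a learned-positional model's capacity (or an explicit `window`) are
truncated to a contiguous slice *centered on the variant*: when both flanks
overflow, the variant lands at `window %/% 2` (floor, ties toward the left
flank); at sequence ends the window clips to the edge.

## LoRA

Low-rank adaptation attaches a trainable update to a frozen projection
$W$: $h = Wx + s\,B(Ax)$, computed without materializing $BA$. $B$ starts
at zero, so attaching adapters never changes the forward pass until
training begins; $A$ starts from a seeded N(0, 0.02) draw. The scaling
defaults to 1 (i.e. $\alpha = r$), a choice documented rather than claimed
from any source. Default targets are the query, value and output
projections; the query/key/value variant is reachable through `targets=`.
Merging folds $sBA$ into $W$ exactly; detaching returns the untouched base
(bitwise) plus the adapters, which serialize into their own archive so they
can be shared independently of the base weights. The freeze contract —
every base tensor bitwise unchanged through any number of adapter updates —
is asserted, not assumed: the optimizer only ever sees the adapter tensors.

## Quantization

Inference-side weight compression, applied to the attention/feed-forward
projections and LM head (norms, biases and embeddings stay in full
precision):

* **absmax int8** (block size 2048): per block, `codes = round(w/absmax *
  127)`; worst-case round-trip error is `absmax/254` per element.
* **NF4** (block size 64): per block, values normalized by absmax snap to a
  16-level NormalFloat codebook built from standard-normal quantiles (8
  positive, 7 negative, exact 0), normalized to $[-1, 1]$. The codebook is
  deliberately asymmetric — that is how the quantile construction comes
  out. On normally distributed weights NF4 has lower mean-squared error
  than a uniform 16-level grid *as an ensemble property*: at 64 samples per
  block the block absmax is noisy and the uniform grid wins roughly a third
  of individual blocks, so the tests assert the ensemble mean at block size
  64 and the per-block ordering at 1024 samples, where it holds 100/100.
* **Double quantization**: the per-block constants are mean-shifted and
  8-bit absmax-quantized in second-level blocks of 256. Reconstruction
  error is bounded by the shifted absmax over 254; storage drops below
  plain fp32 constants from three first-level blocks upward. Because this
  step is lossy, quantization is idempotent only with double quantization
  off — a property the tests state explicitly.
* **Outlier decomposition**: columns containing any entry above the
  threshold (default 6.0) are held out at higher precision before
  quantization and re-inserted on dequantization; the split reassembles the
  original matrix exactly.

A quantized model here is a model whose projection weights have been passed
through quantize–dequantize; it behaves exactly as a quantized checkpoint
would after loading. The end-to-end degradation check scores 200 random
variants with full-precision and quantized fixtures and requires Spearman
agreement of at least 0.9 for both int8 and NF4.

## Task heads and fine-tuning

Residue embeddings (cls/eos excluded, for length-invariance) are pooled
either by the arithmetic mean or by attention pooling,
$h = \mathrm{softmax}(C (E W_k)^\top / \sqrt{d_k})\,E$, whose learnable
class-token queries aggregate each sequence separately — the softmax
normalizes within a sequence only, which is what makes the layer compatible
with packed batches. One class token is the default; with several, the
pooled rows are concatenated before the head. The head itself is a
two-layer ReLU network with scalar output (hidden width 256 by default,
configurable); binary tasks apply a sigmoid and binary cross-entropy, and
upsample the positive class to match the negative count each epoch.

Training uses Adam (learning rate 1e-4, momentum 0.9/0.999) with the rate
multiplied by 0.9 every 10 epochs across 100 epochs, token-budget
minibatches of 50,000 with 16 steps of gradient accumulation, and a 15%
masking rate for the masked-LM objective — these defaults are the package's
published-schedule configuration; every experiment below overrides only
what it must. "Reduced by 10% every 10 epochs" is implemented as
multiplicative (×0.9 per decade) rather than subtracting 10% of the initial
rate; the choice is the package's own and is logged per epoch so a run's
schedule can be audited exactly. Masking replaces selected residues with
the mask token outright — no 80/10/10 corruption split, the simplest
faithful reading of "mask 15% of tokens". Gradients come from a hand-written
reverse-mode pass through the full architecture (verified against central
finite differences in the test suite); in head-only and LoRA modes the
optimizer state simply never includes base tensors, which makes freeze
conservation structural rather than policed.

Positional-embedding extension resizes a learned positional table to a new
maximum (plus the 2 offset rows), copies the old rows, seeds the new ones,
and marks *only the table* trainable — at width 1280 extended to 4096
positions that is $(4096 + 2) \times 1280 = 5{,}245{,}440$ trainable
parameters. With a corpus supplied, the table is retrained on the masked-LM
objective with 1% of sequences held out for validation.

## Synthetic data: what it emulates, and what it does not

The corpus generator draws protein lengths log-normally with median 414
residues and `sdlog` 0.75, clipped to [20, 5000] — calibrated so that the
median matches real proteomes and roughly 12% of proteins exceed 1000
residues, the two length statistics that make token-count batching matter.
Residues are i.i.d. uniform over the 20 canonical amino acids.

Labels for recovery experiments come from a known generative model: a
random linear projection of the mean-pooled embeddings of a *frozen* base
model, standardized to unit variance, plus Gaussian noise (σ = 0.1), or a
Bernoulli draw through a sigmoid of the same latent. Standardizing the
latent fixes the noise-to-signal ratio by construction, so the recovery
ceiling is known (ρ ≈ 0.995 at σ = 0.1) and a head that learns the signal
must approach it.

What passing these tests shows: the machinery — packing, pooling,
gradients, optimization, bookkeeping — is correct, and a learnable signal
in embedding space is in fact learned. What it does not show: anything
about real proteins. Synthetic sequences have no homology, no conserved
positions, no secondary structure, and the label model is linear in
embedding space by fiat; real melting points or fitness landscapes are
none of these things. Benchmarks on real data additionally require
pretrained weights, which this package deliberately does not ship.

## Problem sizes and numerical choices

The test and acceptance experiments run on a 2-layer, 64-dim, 4-head
fixture model (1-layer/32-dim where only the gradient path matters). The
recovery experiment uses 600 proteins at the full length distribution (500
train / 100 held out), head-only, mean pooling, learning rate 1e-3 for 60
epochs — sizes chosen so the whole suite completes comfortably on one CPU
while the length tail is still heavy enough to exercise token-budget
batching. Layer norm uses ε = 1e-5; GELU is the exact Φ-based form;
softmax subtracts the row maximum; ties in the NF4 snap go to the lower
level (`findInterval` semantics). Degenerate inputs are errors, not
warnings: empty sequences, all-special-token masking candidates, attention
rows with no allowed keys, over-capacity sequences in learned-positional
mode.

## Known limitations

* No GPU path and no fused kernels: the block-diagonal dense evaluation is
  the reference implementation; the package measures correctness, not
  wall-clock performance.
* Training at realistic scale is out of reach of plain R matrix algebra;
  the optimization loops are for correctness experiments at fixture scale.
* Quantized bases are inference-only; fine-tuning on quantized weights is
  deliberately unsupported.
* Attention matrices are not exported for structure/contact prediction;
  the package is sequence-task only.
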