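# protlm

Efficient protein language model (PLM) inference, scoring and fine-tuning
in R.

ESM-style masked language models assign every residue of a protein a
probability given its sequence context. That single capability supports a
surprising range of tasks — scoring how well a model "understands" a
protein (pseudo-perplexity), predicting the effect of missense variants
(masked-marginal scores), and, with a small trained head, predicting
protein properties such as melting point or transcription-factor status.
The practical obstacle is cost: proteins vary enormously in length (median
~400 residues, a heavy tail past 1000), so padded batches waste most of
their compute, and full fine-tuning of large models is out of reach for
most groups.

`protlm` implements the efficiency machinery that makes these workloads
tractable, as a complete, self-contained stack testable on one CPU:

* **Sequence packing + block-diagonal attention.** Variable-length
  sequences are concatenated into one padding-free token stream; attention
  is restricted to within-sequence pairs, so the packed forward pass equals
  running every sequence alone. Batches are built to a *token* budget, not
  a sequence count.
* **Transformer core.** GeLU/post-LN blocks (ESM-1x/ESM2 style) and
  SwiGLU/pre-LN blocks (ESM-C style); learned positional tables (with the
  ESM-1x 2-row offset) and rotary embeddings; masked-LM head; hand-written
  reverse-mode gradients, verified against finite differences.
* **Scoring.** Pseudo-perplexity
  `exp((1/T) Σ_t −log p(x_t | x_\t))` via batched masked copies, and
  masked-marginal variant scores `v = log p(alt) − log p(ref)` (nats), with
  variant-centered truncation for proteins beyond a model's length limit.
* **LoRA.** `h = Wx + B(Ax)` adapters on the attention projections: attach
  (zero-initialized, transparent), train (base weights bitwise frozen),
  merge, detach, serialize separately.
* **Quantization.** Blockwise absmax int8, NF4 (normal-quantile codebook)
  with double-quantized constants, and mixed-precision outlier
  decomposition — inference-side compression with tested error bounds.
* **Task heads + training.** Mean and packing-compatible attention
  pooling, two-layer regression/classification heads, positive-class
  upsampling, Adam with step-decay schedule, token-budget minibatches and
  gradient accumulation; head-only and LoRA fine-tuning.
* **Fixtures.** Generators for realistic synthetic corpora (log-normal
  lengths, median 414) and tiny seeded models, so everything above runs
  end to end without downloads.

Pretrained billion-parameter weights and external benchmark datasets are
deliberately out of scope; every claim the package makes is one its own
tests can check.

## Worked example

```r
library(protlm)

model <- synth_tiny_model(seed = 1)
model
#> <plm_model> 2L/64d/4h gelu rotary, 104,225 parameters

prot <- synth_proteins(fixture_spec(4, median_length = 40, sdlog = 0.3, seed = 8))
nchar(prot$sequence)
#> [1] 39 51 35 34

# token-budget batching: 4 proteins packed into 2 balanced batches
plan <- plan_token_batches(nchar(prot$sequence) + 2, max_tokens = 100, seed = 0)
plan$report
#>   batch n_sequences n_tokens utilization oversized
#> 1     1           2       73        0.73     FALSE
#> 2     2           2       94        0.94     FALSE

# pseudo-perplexity: ~33 (the vocab size) for a random untrained model
pseudo_perplexity(model, prot$sequence[1])
#> [1] 32.63772

# masked-marginal scores for two substitutions in protein 1
vt <- data.frame(protein_id = prot$id[1], position = c(5L, 12L),
                 ref = substring(prot$sequence[1], c(5, 12), c(5, 12)),
                 alt = c("W", "A"))
score_variant_table(model, prot, vt)[, c("position", "ref", "alt", "score")]
#>   position ref alt      score
#> 1        5   G   W -0.2282366
#> 2       12   I   A -0.2380043
```

The pseudo-perplexity of an untrained model sits at the vocabulary size
(maximum uncertainty); training pushes it toward 1. Negative
masked-marginal scores mean the model considers the substitution less
likely than the reference residue — under a trained model, a proxy for
deleteriousness.

A 4-bit quantized tensor keeps ~26% of the half-precision footprint:

```r
q <- quantize_nf4(matrix(rnorm(4096), 64, 64))
q
#> <quantized_tensor> 64x64, 4-bit, block 64, 64 blocks, double-quantized constants (2128 bytes)
```

## Command line

A thin CLI over the same functions is installed at
`system.file("cli", "protlm", package = "protlm")`:

```sh
protlm make-fixtures --out-dir fx --n 100 --seed 3
protlm ppl       --fasta fx/proteins.fasta --weights fx/model.rds --out ppl.tsv
protlm variants  --fasta fx/proteins.fasta --variants vars.tsv \
                 --weights fx/model.rds --out scores.tsv --quantize nf4
protlm pack-stats --fasta fx/proteins.fasta --max-tokens 16384 --out pack.tsv
protlm finetune  --fasta fx/proteins.fasta --labels labels.tsv \
                 --weights fx/model.rds --out-dir run1 --lora-rank 16
```

All outputs are TSV with a commented header stating units and conventions
(scores in nats, 1-based positions); repeated invocations reproduce
outputs bitwise.

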