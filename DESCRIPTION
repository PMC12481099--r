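Package: protlm
Title: Efficient Protein Language Model Inference, Scoring and Fine-Tuning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An ESM-style masked protein language model stack built on plain
    matrix algebra: tokenization over the 33-token ESM alphabet, transformer
    blocks with learned or rotary positional encodings, sequence packing with
    block-diagonal attention masks and token-count batching, pseudo-perplexity
    and masked-marginal variant effect scoring, low-rank adaptation (LoRA)
    fine-tuning, blockwise absmax and NF4 weight quantization with outlier
    decomposition, and mean/attention-pooling task heads for regression and
    binary classification. Includes synthetic-corpus and tiny-model fixture
    generators so every component is testable end to end on a single CPU
    without pretrained weights or downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, Biostrings, yaml
Suggests: testthat (>= 3.0.0), withr, pROC
Config/testthat/edition: 3
RoxygenNote: 7.3.3
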