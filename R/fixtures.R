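# Synthetic fixtures: tiny randomly initialized models and protein corpora
# with a known label-generating process, so every component of the stack can
# be exercised end to end without pretrained weights or downloads.

new_plm_model <- function(config, weights, adapters = NULL, lora = NULL) {
  stopifnot(inherits(config, "plm_config"), is.list(weights))
  structure(list(config = config, weights = weights, adapters = adapters,
                 lora = lora),
            class = "plm_model")
}

init_weights <- function(config, seed = 0L, init_sd = 0.02) {
  rmat <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = init_sd), nr, nc)
  with_seed(seed, {
    d <- config$embed_dim
    f <- config$ffn_dim
    V <- config$vocab_size
    W <- list()
    W[["embed_tokens.weight"]] <- rmat(V, d)
    if (config$positional_mode == "learned") {
      W[["embed_positions.weight"]] <- rmat(config$max_positions + POS_OFFSET, d)
    }
    f1_out <- if (config$activation == "swiglu") 2L * f else f
    for (i in seq_len(config$num_layers) - 1L) {
      for (t in c("q", "k", "v", "out")) {
        W[[sprintf("layers.%d.attn.%s.weight", i, t)]] <- rmat(d, d)
        W[[sprintf("layers.%d.attn.%s.bias", i, t)]] <- numeric(d)
      }
      W[[sprintf("layers.%d.attn_norm.weight", i)]] <- rep(1, d)
      W[[sprintf("layers.%d.attn_norm.bias", i)]] <- numeric(d)
      W[[sprintf("layers.%d.ffn.fc1.weight", i)]] <- rmat(f1_out, d)
      W[[sprintf("layers.%d.ffn.fc1.bias", i)]] <- numeric(f1_out)
      W[[sprintf("layers.%d.ffn.fc2.weight", i)]] <- rmat(d, f)
      W[[sprintf("layers.%d.ffn.fc2.bias", i)]] <- numeric(d)
      W[[sprintf("layers.%d.ffn_norm.weight", i)]] <- rep(1, d)
      W[[sprintf("layers.%d.ffn_norm.bias", i)]] <- numeric(d)
    }
    if (!config$tie_lm_head) W[["lm_head.weight"]] <- rmat(V, d)
    W[["lm_head.bias"]] <- numeric(V)
    W
  })
}

#' Generate a tiny randomly initialized model
#'
#' Builds a `plm_model` with seeded Gaussian weights (sd 0.02, the usual
#' transformer init scale), unit layer norms and zero biases. The default
#' configuration — 2 layers, width 64, 4 heads — is the fixture used
#' throughout the test suite: large enough to be non-degenerate, small
#' enough that a full forward pass costs microseconds on one CPU.
#'
#' @param config A [model_config()]; default is the 2-layer/64-dim fixture.
#' @param seed Integer seed; the same seed always yields identical weights.
#' @return A `plm_model`.
#' @examples
#' m <- synth_tiny_model(seed = 1)
#' logits <- forward_logits(tokenize("MKTAYIAK"), m)
#' dim(logits)   # 10 tokens x 33 vocab
#' @export
synth_tiny_model <- function(config = model_config(num_layers = 2L,
                                                   embed_dim = 64L,
                                                   num_heads = 4L),
                             seed = 0L) {
  new_plm_model(config, init_weights(config, seed))
}

#' Specification of a synthetic protein corpus
#'
#' Protein lengths are drawn log-normally. The defaults mirror the length
#' statistics of real proteomes: median 414 residues and a heavy right tail
#' with roughly 12% of proteins longer than 1000 residues (sdlog 0.75 gives
#' P(L > 1000) ~= 0.12 at that median). Lengths are clipped to [20, 5000].
#' Residues are i.i.d. uniform over the 20 canonical amino acids.
#'
#' @param n_proteins Number of proteins.
#' @param median_length Median of the length distribution (residues).
#' @param sdlog Log-scale standard deviation of the length distribution.
#' @param seed Integer seed; generation is fully reproducible.
#' @param label One of `"none"`, `"linear"`, `"logistic"`: the label model
#'   applied by [synth_proteins()] when a base model is supplied.
#' @param noise_sd Noise standard deviation for the linear label model; the
#'   latent signal is standardized to unit variance across the corpus, so
#'   this is also the noise-to-signal ratio.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_proteins, median_length = 414, sdlog = 0.75,
                         seed = 0L, label = c("none", "linear", "logistic"),
                         noise_sd = 0.1) {
  label <- match.arg(label)
  stopifnot(n_proteins >= 1, median_length >= 20, sdlog > 0, noise_sd >= 0)
  structure(list(n_proteins = as.integer(n_proteins),
                 median_length = median_length, sdlog = sdlog,
                 seed = as.integer(seed), label = label,
                 noise_sd = noise_sd),
            class = "fixture_spec")
}

CANONICAL_AA <- c("L", "A", "G", "V", "S", "E", "R", "T", "I", "D",
                  "P", "K", "Q", "N", "F", "Y", "M", "H", "W", "C")

#' Generate a synthetic protein corpus (optionally with labels)
#'
#' Draws proteins according to a [fixture_spec()]. When the spec requests a
#' label model, a frozen base model must be supplied: per-protein labels are
#' generated from a random linear projection of the mean-pooled residue
#' embeddings — `y = w* . mean_pool(E) + eps` for the linear model (latent
#' signal standardized to unit variance, Gaussian noise `noise_sd`), or a
#' Bernoulli draw through a sigmoid of the same latent for the logistic
#' model. Because the generating process is known, downstream fine-tuning
#' can be tested as a parameter-recovery problem.
#'
#' @param spec A [fixture_spec()].
#' @param model A `plm_model`, required when `spec$label != "none"`.
#' @return A data.frame with columns `id`, `sequence` and, when labels are
#'   generated, `label`; the effect vector is attached as attribute
#'   `"effect"` and the noise-free latent as `"latent"`.
#' @export
synth_proteins <- function(spec, model = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  recs <- with_seed(spec$seed, {
    lens <- round(stats::rlnorm(spec$n_proteins,
                                meanlog = log(spec$median_length),
                                sdlog = spec$sdlog))
    lens <- pmin(pmax(lens, 20L), 5000L)
    seqs <- vapply(lens, function(l) {
      paste(sample(CANONICAL_AA, l, replace = TRUE), collapse = "")
    }, character(1))
    data.frame(id = sprintf("prot%05d", seq_len(spec$n_proteins)),
               sequence = seqs, stringsAsFactors = FALSE)
  })
  if (spec$label == "none") return(recs)
  if (is.null(model)) {
    stop("a base model is required to generate '", spec$label, "' labels",
         call. = FALSE)
  }
  H <- pooled_embeddings(model, recs$sequence)
  with_seed(spec$seed + 1L, {
    effect <- stats::rnorm(ncol(H)) / sqrt(ncol(H))
    z <- drop(H %*% effect)
    z <- (z - mean(z)) / stats::sd(z)
    if (spec$label == "linear") {
      recs$label <- z + stats::rnorm(nrow(recs), sd = spec$noise_sd)
    } else {
      recs$label <- stats::rbinom(nrow(recs), 1L, stats::plogis(2 * z))
    }
    attr(recs, "effect") <- effect
    attr(recs, "latent") <- z
  })
  recs
}

# mean-pooled residue embeddings (cls/eos excluded), one row per sequence;
# forward passes are batched under a token budget
pooled_embeddings <- function(model, sequences, max_tokens = 4096L) {
  toks <- lapply(sequences, tokenize)
  plan <- plan_token_batches(lengths(toks), max_tokens, seed = 0L)
  H <- matrix(0, length(sequences), model$config$embed_dim)
  for (bi in plan$batches) {
    pb <- pack(toks[bi])
    hid <- forward_hidden(pb, model)
    per_seq <- unpack(pb, hid)
    for (j in seq_along(bi)) {
      E <- per_seq[[j]]
      H[bi[j], ] <- colMeans(E[2:(nrow(E) - 1L), , drop = FALSE])
    }
  }
  H
}
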