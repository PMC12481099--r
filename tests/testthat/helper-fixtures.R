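# Shared fixtures: tiny models and random sequences, built once per run.

tiny_cfg <- model_config(num_layers = 2L, embed_dim = 64L, num_heads = 4L)

tiny_model <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 1L, config = tiny_cfg) {
    key <- paste0(format(config), "#", seed)
    if (is.null(cache[[key]])) cache[[key]] <- synth_tiny_model(config, seed)
    cache[[key]]
  }
})

learned_cfg <- function(max_positions = 64L, dim = 64L) {
  model_config(num_layers = 2L, embed_dim = dim, num_heads = 4L,
               positional_mode = "learned", max_positions = max_positions)
}

# uniform random sequence over the 20 canonical amino acids
random_aa <- function(n, seed = NULL) {
  draw <- function() paste(sample(protlm:::CANONICAL_AA, n, replace = TRUE),
                           collapse = "")
  if (is.null(seed)) draw() else protlm:::with_seed(seed, draw())
}

# model whose logits are constant (uniform distribution over the vocab)
uniform_model <- function(seed = 1L) {
  m <- tiny_model(seed)
  m$weights$lm_head.weight[] <- 0
  m$weights$lm_head.bias[] <- 0
  m
}
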