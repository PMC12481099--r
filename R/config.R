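#' Architecture hyperparameters for an ESM-style model
#'
#' Describes one transformer variant. Two families are in common use: the
#' GeLU / post-layer-norm blocks of ESM-1b/ESM-1v/ESM2 (learned or rotary
#' positions) and the SwiGLU / pre-layer-norm blocks of ESM-C (rotary).
#'
#' @param num_layers Number of transformer blocks.
#' @param embed_dim Embedding width; must be divisible by `num_heads`.
#' @param num_heads Attention heads per block.
#' @param ffn_dim Hidden width of the feed-forward sublayer.
#' @param vocab_size Token vocabulary size (33 for the ESM alphabet).
#' @param max_positions Longest supported sequence (tokens, including
#'   cls/eos) in learned-positional mode; ignored for rotary.
#' @param positional_mode `"learned"` (position embedding table, ESM-1x
#'   style) or `"rotary"` (ESM2/ESM-C style).
#' @param activation `"gelu"` or `"swiglu"` feed-forward activation.
#' @param norm_style `"post"` (residual then layer norm) or `"pre"` (layer
#'   norm then sublayer). Defaults follow the family convention: post-LN with
#'   gelu, pre-LN with swiglu.
#' @param tie_lm_head Tie the LM-head projection to the token embedding
#'   table instead of keeping separate weights.
#' @return An object of class `plm_config`.
#' @examples
#' model_config(num_layers = 2, embed_dim = 64, num_heads = 4)
#' @export
model_config <- function(num_layers, embed_dim, num_heads,
                         ffn_dim = 4L * embed_dim,
                         vocab_size = 33L,
                         max_positions = 1024L,
                         positional_mode = c("rotary", "learned"),
                         activation = c("gelu", "swiglu"),
                         norm_style = NULL,
                         tie_lm_head = FALSE) {
  positional_mode <- match.arg(positional_mode)
  activation <- match.arg(activation)
  if (is.null(norm_style)) {
    norm_style <- if (activation == "swiglu") "pre" else "post"
  }
  norm_style <- match.arg(norm_style, c("pre", "post"))
  stopifnot(
    num_layers >= 1, embed_dim >= 2, num_heads >= 1,
    ffn_dim >= 1, vocab_size >= 4
  )
  if (embed_dim %% num_heads != 0) {
    stop("embed_dim must be divisible by num_heads", call. = FALSE)
  }
  if ((embed_dim %/% num_heads) %% 2L != 0L && positional_mode == "rotary") {
    stop("rotary positions require an even per-head dimension", call. = FALSE)
  }
  if (positional_mode == "learned" && max_positions < 2) {
    stop("max_positions must be >= 2 in learned mode", call. = FALSE)
  }
  structure(
    list(
      num_layers = as.integer(num_layers),
      embed_dim = as.integer(embed_dim),
      num_heads = as.integer(num_heads),
      head_dim = as.integer(embed_dim %/% num_heads),
      ffn_dim = as.integer(ffn_dim),
      vocab_size = as.integer(vocab_size),
      max_positions = as.integer(max_positions),
      positional_mode = positional_mode,
      activation = activation,
      norm_style = norm_style,
      tie_lm_head = isTRUE(tie_lm_head)
    ),
    class = "plm_config"
  )
}

#' @export
print.plm_config <- function(x, ...) {
  cat(sprintf(
    "<plm_config> %d layers, dim %d (%d heads), ffn %d, vocab %d, %s positions, %s/%s-LN\n",
    x$num_layers, x$embed_dim, x$num_heads, x$ffn_dim, x$vocab_size,
    x$positional_mode, x$activation, x$norm_style
  ))
  invisible(x)
}

# number of rows reserved at the top of the learned positional table; the
# ESM-1x convention offsets positions by the padding index + 1
POS_OFFSET <- 2L

#' Total parameter count of a model
#'
#' @param model A `plm_model`.
#' @return Integer-valued numeric (may exceed .Machine$integer.max for large
#'   configurations).
#' @export
n_parameters <- function(model) {
  stopifnot(inherits(model, "plm_model"))
  sum(vapply(model$weights, function(w) as.numeric(length(w)), numeric(1)))
}
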