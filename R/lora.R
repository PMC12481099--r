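# Low-rank adaptation (LoRA). A frozen projection W (n x m) gains a
# trainable update: h = Wx + scaling * B(Ax), with A (r x m) seeded small
# random and B (n x r) zero, so a fresh adapter leaves the forward pass
# bitwise unchanged. Only A and B train; the base weights stay frozen,
# which is what makes adapters cheap and immune to catastrophic forgetting.

LORA_TARGETS <- c("q", "k", "v", "out")

#' Low-rank adapted linear map
#'
#' Computes `h = W x + scaling * B (A x)` for a single input or a matrix of
#' row-vector inputs, without materializing the dense update `B A`.
#'
#' @param W Frozen weight matrix `[n x m]`.
#' @param adapter List with `A` (`[r x m]`), `B` (`[n x r]`) and `scaling`.
#' @param x Input: vector of length `m` or matrix `[rows x m]`.
#' @return Matrix `[rows x n]` (a 1-row matrix for vector input).
#' @export
lora_forward <- function(W, adapter, x) {
  if (!is.matrix(x)) x <- matrix(x, nrow = 1L)
  if (ncol(x) != ncol(W) || ncol(x) != ncol(adapter$A) ||
      nrow(adapter$B) != nrow(W) || ncol(adapter$B) != nrow(adapter$A)) {
    stop("LoRA shapes do not conform", call. = FALSE)
  }
  linear_fwd(x, W, b = NULL, adapter = adapter)$y
}

#' Attach LoRA adapters to a model
#'
#' Adds rank-`r` adapters to the chosen attention projections of every
#' transformer layer. `B` is initialized to zero and `A` from a seeded
#' N(0, 0.02) draw, so the adapted model's forward pass is identical to the
#' base model until training begins. Base weights are marked frozen.
#'
#' @param model A non-adapted `plm_model`.
#' @param rank Adapter rank `r` (must satisfy `r <= embed_dim`).
#' @param targets Subset of `c("q", "k", "v", "out")`; the default `q, v,
#'   out` follows common practice for attention-layer adapters.
#' @param scaling Multiplier on the low-rank update (alpha / r); default 1.
#' @param seed Seed for the `A` initialization.
#' @return An adapted `plm_model`.
#' @export
lora_attach <- function(model, rank = 16L, targets = c("q", "v", "out"),
                        scaling = 1, seed = 0L) {
  stopifnot(inherits(model, "plm_model"))
  if (!is.null(model$adapters)) {
    stop("model already has adapters attached", call. = FALSE)
  }
  bad <- setdiff(targets, LORA_TARGETS)
  if (length(bad) > 0L) {
    stop("unknown LoRA target(s): ", paste(bad, collapse = ", "),
         "; valid targets are ", paste(LORA_TARGETS, collapse = ", "),
         call. = FALSE)
  }
  d <- model$config$embed_dim
  if (rank > d) stop("rank must be <= embed_dim", call. = FALSE)
  adapters <- with_seed(seed, {
    out <- list()
    for (li in seq_len(model$config$num_layers) - 1L) {
      for (t in targets) {
        out[[sprintf("layers.%d.attn.%s", li, t)]] <- list(
          A = matrix(stats::rnorm(rank * d, sd = 0.02), rank, d),
          B = matrix(0, d, rank),
          scaling = scaling
        )
      }
    }
    out
  })
  new_plm_model(model$config, model$weights, adapters = adapters,
                lora = list(rank = as.integer(rank), targets = targets,
                            scaling = scaling))
}

#' Merge adapters into the base weights
#'
#' Folds every adapter into its frozen projection (`W <- W + scaling * B A`)
#' and returns a plain, non-adapted model whose forward pass equals the
#' adapted model's.
#'
#' @param model An adapted `plm_model`.
#' @return A plain `plm_model`.
#' @export
lora_merge <- function(model) {
  if (is.null(model$adapters)) {
    stop("model has no adapters to merge", call. = FALSE)
  }
  W <- model$weights
  for (nm in names(model$adapters)) {
    ad <- model$adapters[[nm]]
    key <- paste0(nm, ".weight")
    W[[key]] <- W[[key]] + ad$scaling * (ad$B %*% ad$A)
  }
  new_plm_model(model$config, W)
}

#' Detach adapters from a model
#'
#' @param model An adapted `plm_model`.
#' @return List with `base` (the unmodified base model, forward bitwise
#'   equal to the original) and `adapters` (the adapter tensors).
#' @export
lora_detach <- function(model) {
  if (is.null(model$adapters)) {
    stop("model has no adapters to detach", call. = FALSE)
  }
  list(base = new_plm_model(model$config, model$weights),
       adapters = model$adapters, lora = model$lora)
}

#' Trainable-parameter count of the adapters
#'
#' For rank `r` adapters on `k` targets of an `L`-layer, `d`-dim model the
#' count is `L * k * 2 * r * d`.
#'
#' @param model An adapted `plm_model`.
#' @return Numeric count.
#' @export
lora_n_trainable <- function(model) {
  if (is.null(model$adapters)) return(0)
  sum(vapply(model$adapters,
             function(a) as.numeric(length(a$A) + length(a$B)), numeric(1)))
}
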