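# Task heads for downstream prediction on frozen (or LoRA-adapted)
# embeddings: mean pooling, packing-compatible attention pooling, a
# two-layer regression head and its sigmoid classification variant, plus
# positive-class upsampling for imbalanced binary tasks. Pooling operates
# on residue embeddings only; cls/eos rows are excluded so the pooled
# vector is comparable across sequence lengths.

#' Mean-pool residue embeddings
#'
#' Arithmetic mean over the residue positions of one sequence:
#' `h = (1/N) * sum_i e_i`.
#'
#' @param E Matrix `[N x d]` of residue embeddings (special tokens already
#'   excluded), N >= 1.
#' @return Numeric vector of length `d`.
#' @export
mean_pool <- function(E) {
  if (!is.matrix(E) || nrow(E) == 0L) {
    stop("mean_pool requires at least one residue embedding", call. = FALSE)
  }
  colMeans(E)
}

#' Create a two-layer regression head
#'
#' `y = W2 ReLU(W1 h + b1) + b2`, scalar output. Weights are seeded
#' N(0, sd) with sd scaled by fan-in; biases start at zero.
#'
#' @param d_in Input (embedding) width.
#' @param hidden Hidden width; default 256.
#' @param seed Integer seed.
#' @return A `regression_head` list with `W1, b1, W2, b2`.
#' @export
regression_head <- function(d_in, hidden = 256L, seed = 0L) {
  with_seed(seed, {
    structure(list(
      W1 = matrix(stats::rnorm(hidden * d_in, sd = 1 / sqrt(d_in)), hidden, d_in),
      b1 = numeric(hidden),
      W2 = matrix(stats::rnorm(hidden, sd = 1 / sqrt(hidden)), 1L, hidden),
      b2 = 0
    ), class = "regression_head")
  })
}

#' Regression head forward pass
#'
#' @param h Pooled embedding: vector of length `d_in` or matrix
#'   `[n x d_in]`.
#' @param head A [regression_head()].
#' @return Numeric vector of predictions, one per row of `h`.
#' @export
regression_forward <- function(h, head) {
  if (!is.matrix(h)) h <- matrix(h, nrow = 1L)
  if (ncol(h) != ncol(head$W1)) {
    stop(sprintf("h has width %d but head expects %d", ncol(h),
                 ncol(head$W1)), call. = FALSE)
  }
  a <- sweep(h %*% t(head$W1), 2L, head$b1, `+`)
  drop(pmax(a, 0) %*% t(head$W2)) + head$b2
}

#' Binary classification forward pass
#'
#' Sigmoid of the regression head's output: probability in (0, 1).
#'
#' @inheritParams regression_forward
#' @export
classify_forward <- function(h, head) {
  stats::plogis(regression_forward(h, head))
}

# head forward keeping pre-activations, and its backward
head_fwd <- function(h, head) {
  a <- sweep(h %*% t(head$W1), 2L, head$b1, `+`)
  r <- pmax(a, 0)
  list(y = drop(r %*% t(head$W2)) + head$b2, a = a, r = r, h = h)
}

head_bwd <- function(dy, cache, head) {
  dy <- matrix(dy, ncol = 1L)
  dW2 <- crossprod(dy, cache$r)
  db2 <- sum(dy)
  dr <- dy %*% head$W2
  da <- dr * (cache$a > 0)
  list(grads = list(W1 = crossprod(da, cache$h), b1 = colSums(da),
                    W2 = dW2, b2 = db2),
       dh = da %*% head$W1)
}

#' Create an attention-pooling layer
#'
#' Learnable class-token queries `C` (`n_class_tokens x d_k`) attend over a
#' sequence's embeddings through a key projection `Wk` (`d_k x d`):
#' `h = softmax(C (E Wk)^T / sqrt(d_k)) E`. Unlike mean pooling the
#' aggregation weights are learned, and the softmax is normalized within
#' each sequence only, which makes the layer compatible with packed
#' batches.
#'
#' @param d Embedding width of the base model.
#' @param d_k Key width (the softmax normalization constant).
#' @param n_class_tokens Number of learnable query tokens; their pooled
#'   rows are concatenated before the head when > 1.
#' @param seed Integer seed.
#' @return An `attention_pooling` list with `C`, `Wk`, `d_k`.
#' @export
attention_pooling <- function(d, d_k = d, n_class_tokens = 1L, seed = 0L) {
  with_seed(seed, {
    structure(list(
      C = matrix(stats::rnorm(n_class_tokens * d_k, sd = 1 / sqrt(d_k)),
                 n_class_tokens, d_k),
      Wk = matrix(stats::rnorm(d_k * d, sd = 1 / sqrt(d)), d_k, d),
      d_k = as.integer(d_k)
    ), class = "attention_pooling")
  })
}

#' Attention-pool one sequence's embeddings
#'
#' @param E Matrix `[N x d]` of residue embeddings, N >= 1.
#' @param pooling An [attention_pooling()].
#' @return Matrix `[n_class_tokens x d]`; attention weights per class token
#'   are nonnegative and sum to 1 over the sequence.
#' @export
attention_pool <- function(E, pooling) {
  if (!is.matrix(E) || nrow(E) == 0L) {
    stop("attention_pool requires a non-empty embedding matrix", call. = FALSE)
  }
  K <- E %*% t(pooling$Wk)                        # [N x d_k]
  P <- softmax_rows(pooling$C %*% t(K) / sqrt(pooling$d_k))
  P %*% E
}

attention_pool_fwd <- function(E, pooling) {
  K <- E %*% t(pooling$Wk)
  S <- pooling$C %*% t(K) / sqrt(pooling$d_k)
  P <- softmax_rows(S)
  list(h = P %*% E, P = P, K = K, E = E)
}

attention_pool_bwd <- function(dh, cache, pooling) {
  sq <- sqrt(pooling$d_k)
  dP <- dh %*% t(cache$E)
  dE <- crossprod(cache$P, dh)
  dS <- cache$P * (dP - rowSums(dP * cache$P))
  dC <- dS %*% cache$K / sq
  dK <- crossprod(dS, pooling$C) / sq
  dWk <- crossprod(dK, cache$E)
  dE <- dE + dK %*% pooling$Wk
  list(grads = list(C = dC, Wk = dWk), dE = dE)
}

#' Upsample the positive class
#'
#' Index multiset for one epoch of balanced training on an imbalanced
#' binary task: negatives are kept as-is and positives are resampled with
#' replacement until both classes have equal counts. Already-balanced input
#' returns the identity multiset. Deterministic per seed.
#'
#' @param labels Binary vector (0/1 or logical); both classes must be
#'   present.
#' @param seed Integer seed.
#' @return Integer index vector into `labels`, with equal class counts.
#' @export
upsample_positive <- function(labels, seed = 0L) {
  y <- as.integer(labels)
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (length(pos) == 0L || length(neg) == 0L) {
    stop("both classes must be present to upsample", call. = FALSE)
  }
  if (length(pos) == length(neg)) return(seq_along(y))
  drawn <- with_seed(seed, sample(pos, length(neg), replace = TRUE))
  sort(c(neg, drawn))
}
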