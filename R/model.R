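# Transformer forward pass on plain matrices.
#
# Conventions: activations are [tokens x embed_dim] row-major matrices;
# projection weights are stored [out_dim x in_dim] so y = x %*% t(W) + b,
# matching the layout of common named-tensor archives. Token ids and
# positions are 0-based; positions restart at every sequence boundary in a
# packed batch, so each protein sees its own coordinates.

LN_EPS <- 1e-5

linear_fwd <- function(x, W, b = NULL, adapter = NULL) {
  y <- x %*% t(W)
  if (!is.null(b)) y <- sweep(y, 2L, b, `+`)
  u <- NULL
  if (!is.null(adapter)) {
    # h = Wx + scaling * B(Ax), computed without materializing BA
    u <- x %*% t(adapter$A)
    y <- y + adapter$scaling * (u %*% t(adapter$B))
  }
  list(y = y, u = u)
}

layer_norm_fwd <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv_sd <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv_sd
  y <- sweep(xhat, 2L, g, `*`)
  y <- sweep(y, 2L, b, `+`)
  list(y = y, xhat = xhat, inv_sd = inv_sd)
}

gelu <- function(x) x * stats::pnorm(x)
gelu_grad <- function(x) stats::pnorm(x) + x * stats::dnorm(x)
silu <- function(x) x * stats::plogis(x)
silu_grad <- function(x) {
  s <- stats::plogis(x)
  s * (1 + x * (1 - s))
}

softmax_rows <- function(S) {
  m <- S[cbind(seq_len(nrow(S)), max.col(S, ties.method = "first"))]
  E <- exp(S - m)
  E / rowSums(E)
}

#' Rotary position embedding
#'
#' Rotates each per-head vector by position-dependent angles: the head
#' dimension is split in half and each pair `(x_j, x_{j + d/2})` is rotated
#' in its plane by `pos * theta_j` with `theta_j = 10000^(-2(j-1)/d)`.
#' Rotations are isometries, and query/key dot products depend only on the
#' relative offset between positions — the property that makes rotary
#' embeddings extrapolate across absolute positions.
#'
#' @param x Matrix `[tokens x head_dim]` with `head_dim` even.
#' @param positions Integer vector of 0-based absolute positions, one per
#'   row of `x`.
#' @param invert Apply the inverse rotation (used in the backward pass).
#' @return Rotated matrix, same shape as `x`.
#' @export
apply_rotary <- function(x, positions, invert = FALSE) {
  d <- ncol(x)
  if (d %% 2L != 0L) stop("rotary requires an even head dimension", call. = FALSE)
  if (length(positions) != nrow(x)) {
    stop("one position per row of x is required", call. = FALSE)
  }
  half <- d %/% 2L
  theta <- 10000^(-(2 * (seq_len(half) - 1)) / d)
  ang <- outer(as.numeric(positions), theta)    # [tokens x half]
  if (invert) ang <- -ang
  co <- cos(ang); si <- sin(ang)
  x1 <- x[, seq_len(half), drop = FALSE]
  x2 <- x[, half + seq_len(half), drop = FALSE]
  cbind(x1 * co - x2 * si, x2 * co + x1 * si)
}

#' Scaled dot-product self-attention
#'
#' Reference (dense-mask) attention: `out[i] = sum_j softmax_j(q_i . k_j /
#' sqrt(d), over allowed j) v_j`. The mask marks which query/key pairs are
#' allowed; for a packed batch this is the block-diagonal mask, which makes
#' the packed computation equal to per-sequence attention.
#'
#' @param q,k,v Matrices with one row per token; `q` and `k` share their
#'   column dimension.
#' @param mask Logical `[nrow(q) x nrow(k)]` matrix of allowed pairs, or
#'   NULL for all-allowed.
#' @param d Normalization constant; defaults to the per-head key dimension
#'   `ncol(k)`.
#' @return List with `out` (`[nrow(q) x ncol(v)]`) and `p` (the attention
#'   weight matrix, rows summing to 1).
#' @export
self_attention <- function(q, k, v, mask = NULL, d = ncol(k)) {
  stopifnot(ncol(q) == ncol(k), nrow(k) == nrow(v))
  S <- q %*% t(k) / sqrt(d)
  if (!is.null(mask)) {
    stopifnot(is.logical(mask), nrow(mask) == nrow(q), ncol(mask) == nrow(k))
    if (any(rowSums(mask) == 0L)) {
      stop("query row(s) with zero allowed keys cannot be normalized",
           call. = FALSE)
    }
    S[!mask] <- -Inf
  }
  P <- softmax_rows(S)
  list(out = P %*% v, p = P)
}

# one attention sublayer on already-normalized input; block-diagonal
# structure is exploited by evaluating each sequence's block separately
# (bit-identical to the dense -Inf-masked evaluation restricted per block).
attn_sublayer_fwd <- function(xn, model, li, boundaries, positions,
                              keep = FALSE) {
  cfg <- model$config
  W <- model$weights
  pre <- sprintf("layers.%d.attn", li - 1L)
  ad <- function(t) model$adapters[[sprintf("%s.%s", pre, t)]]
  gq <- linear_fwd(xn, W[[paste0(pre, ".q.weight")]], W[[paste0(pre, ".q.bias")]], ad("q"))
  gk <- linear_fwd(xn, W[[paste0(pre, ".k.weight")]], W[[paste0(pre, ".k.bias")]], ad("k"))
  gv <- linear_fwd(xn, W[[paste0(pre, ".v.weight")]], W[[paste0(pre, ".v.bias")]], ad("v"))
  q <- gq$y; k <- gk$y; v <- gv$y
  H <- cfg$num_heads; dh <- cfg$head_dim
  qr <- q; kr <- k
  if (cfg$positional_mode == "rotary") {
    for (h in seq_len(H)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      qr[, cols] <- apply_rotary(q[, cols, drop = FALSE], positions)
      kr[, cols] <- apply_rotary(k[, cols, drop = FALSE], positions)
    }
  }
  nseq <- length(boundaries) - 1L
  o <- matrix(0, nrow(xn), ncol(xn))
  Ps <- if (keep) vector("list", nseq) else NULL
  for (s in seq_len(nseq)) {
    idx <- (boundaries[s] + 1L):boundaries[s + 1L]
    if (keep) Ps[[s]] <- vector("list", H)
    for (h in seq_len(H)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      att <- self_attention(qr[idx, cols, drop = FALSE],
                            kr[idx, cols, drop = FALSE],
                            v[idx, cols, drop = FALSE], d = dh)
      o[idx, cols] <- att$out
      if (keep) Ps[[s]][[h]] <- att$p
    }
  }
  go <- linear_fwd(o, W[[paste0(pre, ".out.weight")]], W[[paste0(pre, ".out.bias")]], ad("out"))
  out <- list(y = go$y)
  if (keep) {
    out$cache <- list(xn = xn, q = q, k = k, qr = qr, kr = kr, v = v, o = o,
                      P = Ps, uq = gq$u, uk = gk$u, uv = gv$u, uo = go$u)
  }
  out
}

ffn_sublayer_fwd <- function(xn, model, li, keep = FALSE) {
  cfg <- model$config
  W <- model$weights
  pre <- sprintf("layers.%d.ffn", li - 1L)
  a1 <- linear_fwd(xn, W[[paste0(pre, ".fc1.weight")]], W[[paste0(pre, ".fc1.bias")]])$y
  if (cfg$activation == "gelu") {
    act <- gelu(a1)
    g <- NULL; u <- NULL
  } else {
    # SwiGLU: fc1 emits [gate | value]; hidden = silu(gate) * value
    f <- cfg$ffn_dim
    g <- a1[, seq_len(f), drop = FALSE]
    u <- a1[, f + seq_len(f), drop = FALSE]
    act <- silu(g) * u
  }
  y <- linear_fwd(act, W[[paste0(pre, ".fc2.weight")]], W[[paste0(pre, ".fc2.bias")]])$y
  out <- list(y = y)
  if (keep) out$cache <- list(xn = xn, a1 = a1, act = act, g = g, u = u)
  out
}

# one transformer block; post-LN: x -> LN(x + attn(x)) -> LN(. + ffn(.))
#                        pre-LN:  x -> x + attn(LN(x)) -> . + ffn(LN(.))
block_fwd <- function(x, model, li, boundaries, positions, keep = FALSE) {
  cfg <- model$config
  W <- model$weights
  ng <- W[[sprintf("layers.%d.attn_norm.weight", li - 1L)]]
  nb <- W[[sprintf("layers.%d.attn_norm.bias", li - 1L)]]
  mg <- W[[sprintf("layers.%d.ffn_norm.weight", li - 1L)]]
  mb <- W[[sprintf("layers.%d.ffn_norm.bias", li - 1L)]]
  cache <- if (keep) list(x_in = x) else NULL

  if (cfg$norm_style == "pre") {
    ln1 <- layer_norm_fwd(x, ng, nb)
    at <- attn_sublayer_fwd(ln1$y, model, li, boundaries, positions, keep)
    h <- x + at$y
    ln2 <- layer_norm_fwd(h, mg, mb)
    ff <- ffn_sublayer_fwd(ln2$y, model, li, keep)
    y <- h + ff$y
    if (keep) cache <- c(cache, list(ln1 = ln1, attn = at$cache, h = h,
                                     ln2 = ln2, ffn = ff$cache))
  } else {
    at <- attn_sublayer_fwd(x, model, li, boundaries, positions, keep)
    r1 <- x + at$y
    ln1 <- layer_norm_fwd(r1, ng, nb)
    ff <- ffn_sublayer_fwd(ln1$y, model, li, keep)
    r2 <- ln1$y + ff$y
    ln2 <- layer_norm_fwd(r2, mg, mb)
    y <- ln2$y
    if (keep) cache <- c(cache, list(attn = at$cache, r1 = r1, ln1 = ln1,
                                     ffn = ff$cache, r2 = r2, ln2 = ln2))
  }
  list(y = y, cache = cache)
}

#' Run one transformer block
#'
#' Applies layer `layer` of a model to a matrix of token embeddings:
#' residual self-attention sublayer followed by a residual feed-forward
#' sublayer, with norm placement, activation and positional mode taken from
#' the model's config. With zero attention-output and feed-forward weights
#' the block reduces (up to layer norm) to the residual identity path.
#'
#' @param x Matrix `[tokens x embed_dim]`.
#' @param model A `plm_model`.
#' @param layer 1-based layer index.
#' @param boundaries Packed-batch boundaries; default treats `x` as one
#'   sequence.
#' @param positions 0-based positions per row; default restarts at each
#'   boundary.
#' @return Updated `[tokens x embed_dim]` matrix.
#' @export
transformer_block <- function(x, model, layer = 1L,
                              boundaries = c(0L, nrow(x)),
                              positions = packed_positions(boundaries)) {
  stopifnot(inherits(model, "plm_model"), is.matrix(x))
  if (ncol(x) != model$config$embed_dim) {
    stop(sprintf("x has %d columns; model embed_dim is %d", ncol(x),
                 model$config$embed_dim), call. = FALSE)
  }
  block_fwd(x, model, layer, boundaries, positions)$y
}

as_packed <- function(input) {
  if (inherits(input, "packed_batch")) input else pack(list(as.integer(input)))
}

# full forward: embeddings -> L blocks -> (hidden, logits)
plm_forward <- function(model, input, keep = FALSE, want_logits = TRUE) {
  cfg <- model$config
  W <- model$weights
  batch <- as_packed(input)
  tokens <- batch$tokens
  if (any(tokens < 0L) || any(tokens >= cfg$vocab_size)) {
    stop("token id out of range for vocab", call. = FALSE)
  }
  b <- batch$boundaries
  seq_lens <- diff(b)
  if (cfg$positional_mode == "learned" && any(seq_lens > cfg$max_positions)) {
    bad <- which(seq_lens > cfg$max_positions)
    stop(sprintf(
      "sequence(s) %s exceed max_positions = %d in learned-positional mode",
      paste(bad, collapse = ", "), cfg$max_positions), call. = FALSE)
  }
  positions <- packed_positions(b)
  x <- W$embed_tokens.weight[tokens + 1L, , drop = FALSE]
  if (cfg$positional_mode == "learned") {
    x <- x + W$embed_positions.weight[positions + POS_OFFSET + 1L, , drop = FALSE]
  }
  caches <- if (keep) vector("list", cfg$num_layers) else NULL
  for (li in seq_len(cfg$num_layers)) {
    bl <- block_fwd(x, model, li, b, positions, keep)
    x <- bl$y
    if (keep) caches[[li]] <- bl$cache
  }
  logits <- NULL
  if (want_logits) {
    hw <- if (cfg$tie_lm_head) W$embed_tokens.weight else W$lm_head.weight
    logits <- linear_fwd(x, hw, W$lm_head.bias)$y
  }
  list(logits = logits, hidden = x,
       cache = if (keep) list(batch = batch, positions = positions,
                              layers = caches, tokens = tokens) else NULL)
}

#' Per-token logits over the vocabulary
#'
#' Runs the full model — embeddings, transformer blocks, LM head — on a
#' token vector or packed batch and returns masked-language-model logits.
#' For a packed batch, attention is restricted by the block-diagonal mask
#' and positions restart at each sequence, so the result equals running
#' each sequence alone (rows concatenated in packing order).
#'
#' @param input Integer token-id vector (one sequence) or a `packed_batch`.
#' @param model A `plm_model`.
#' @return Numeric matrix `[total_tokens x vocab_size]`.
#' @export
forward_logits <- function(input, model) {
  stopifnot(inherits(model, "plm_model"))
  plm_forward(model, input)$logits
}

#' Final hidden states (residue embeddings)
#'
#' Like [forward_logits()] but stops before the LM head, returning the
#' contextual embedding of every token. These are the representations that
#' downstream task heads pool and regress on.
#'
#' @inheritParams forward_logits
#' @return Numeric matrix `[total_tokens x embed_dim]`.
#' @export
forward_hidden <- function(input, model) {
  stopifnot(inherits(model, "plm_model"))
  plm_forward(model, input, want_logits = FALSE)$hidden
}

#' @export
print.plm_model <- function(x, ...) {
  cat(sprintf("<plm_model> %s%s, %s parameters\n",
              format(x$config)[1], if (!is.null(x$adapters)) " + LoRA" else "",
              format(n_parameters(x), big.mark = ",")))
  invisible(x)
}

#' @export
format.plm_config <- function(x, ...) {
  sprintf("%dL/%dd/%dh %s %s", x$num_layers, x$embed_dim, x$num_heads,
          x$activation, x$positional_mode)
}
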