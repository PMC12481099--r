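# Reverse-mode gradients for the transformer, written against the caches
# recorded by plm_forward(..., keep = TRUE). Gradients are returned as a
# flat named list: base-weight names match the weight archive
# ("layers.0.attn.q.weight", ...), adapter gradients are keyed
# "adapters.<layer-name>.A" / ".B".

acc_grad <- function(G, name, val) {
  if (is.null(G$g[[name]])) G$g[[name]] <- val else G$g[[name]] <- G$g[[name]] + val
  invisible(NULL)
}

layer_norm_bwd <- function(dy, ln, g) {
  dxhat <- sweep(dy, 2L, g, `*`)
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * ln$xhat)
  list(dx = (dxhat - m1 - ln$xhat * m2) * ln$inv_sd,
       dg = colSums(dy * ln$xhat),
       db = colSums(dy))
}

# backward of y = x W^T + b [+ s * (x A^T) B^T]; returns dx, accumulates dW,
# db and (if an adapter is present) dA, dB
proj_bwd <- function(G, dy, x, u, wname, adapter, adapter_name) {
  W <- G$W[[paste0(wname, ".weight")]]
  acc_grad(G, paste0(wname, ".weight"), crossprod(dy, x))
  acc_grad(G, paste0(wname, ".bias"), colSums(dy))
  dx <- dy %*% W
  if (!is.null(adapter)) {
    s <- adapter$scaling
    du <- s * (dy %*% adapter$B)
    acc_grad(G, paste0("adapters.", adapter_name, ".B"), s * crossprod(dy, u))
    acc_grad(G, paste0("adapters.", adapter_name, ".A"), crossprod(du, x))
    dx <- dx + du %*% adapter$A
  }
  dx
}

attn_sublayer_bwd <- function(G, dy, cache, model, li, boundaries, positions) {
  cfg <- model$config
  pre <- sprintf("layers.%d.attn", li - 1L)
  ad <- function(t) model$adapters[[sprintf("%s.%s", pre, t)]]
  H <- cfg$num_heads; dh <- cfg$head_dim

  d_o <- proj_bwd(G, dy, cache$o, cache$uo, paste0(pre, ".out"), ad("out"),
                  sprintf("%s.out", pre))
  dqr <- matrix(0, nrow(dy), cfg$embed_dim)
  dkr <- matrix(0, nrow(dy), cfg$embed_dim)
  dv <- matrix(0, nrow(dy), cfg$embed_dim)
  nseq <- length(boundaries) - 1L
  for (s in seq_len(nseq)) {
    idx <- (boundaries[s] + 1L):boundaries[s + 1L]
    for (h in seq_len(H)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      P <- cache$P[[s]][[h]]
      dO <- d_o[idx, cols, drop = FALSE]
      V <- cache$v[idx, cols, drop = FALSE]
      dP <- dO %*% t(V)
      dS <- P * (dP - rowSums(dP * P))
      dv[idx, cols] <- dv[idx, cols] + crossprod(P, dO)
      dqr[idx, cols] <- dS %*% cache$kr[idx, cols, drop = FALSE] / sqrt(dh)
      dkr[idx, cols] <- crossprod(dS, cache$qr[idx, cols, drop = FALSE]) / sqrt(dh)
    }
  }
  dq <- dqr; dk <- dkr
  if (cfg$positional_mode == "rotary") {
    for (h in seq_len(H)) {
      cols <- (h - 1L) * dh + seq_len(dh)
      dq[, cols] <- apply_rotary(dqr[, cols, drop = FALSE], positions, invert = TRUE)
      dk[, cols] <- apply_rotary(dkr[, cols, drop = FALSE], positions, invert = TRUE)
    }
  }
  xn <- cache$xn
  dxn <- proj_bwd(G, dq, xn, cache$uq, paste0(pre, ".q"), ad("q"), paste0(pre, ".q")) +
         proj_bwd(G, dk, xn, cache$uk, paste0(pre, ".k"), ad("k"), paste0(pre, ".k")) +
         proj_bwd(G, dv, xn, cache$uv, paste0(pre, ".v"), ad("v"), paste0(pre, ".v"))
  dxn
}

ffn_sublayer_bwd <- function(G, dy, cache, model, li) {
  cfg <- model$config
  pre <- sprintf("layers.%d.ffn", li - 1L)
  d_act <- proj_bwd(G, dy, cache$act, NULL, paste0(pre, ".fc2"), NULL, NULL)
  if (cfg$activation == "gelu") {
    d_a1 <- d_act * gelu_grad(cache$a1)
  } else {
    d_g <- d_act * cache$u * silu_grad(cache$g)
    d_u <- d_act * silu(cache$g)
    d_a1 <- cbind(d_g, d_u)
  }
  proj_bwd(G, d_a1, cache$xn, NULL, paste0(pre, ".fc1"), NULL, NULL)
}

block_bwd <- function(G, dy, cache, model, li, boundaries, positions) {
  cfg <- model$config
  ng <- sprintf("layers.%d.attn_norm", li - 1L)
  mg <- sprintf("layers.%d.ffn_norm", li - 1L)
  gn <- G$W[[paste0(ng, ".weight")]]
  gm <- G$W[[paste0(mg, ".weight")]]

  if (cfg$norm_style == "pre") {
    # y = h + ffn(LN2(h)); h = x + attn(LN1(x))
    d_h <- dy
    l2 <- layer_norm_bwd(ffn_sublayer_bwd(G, dy, cache$ffn, model, li),
                         cache$ln2, gm)
    acc_grad(G, paste0(mg, ".weight"), l2$dg)
    acc_grad(G, paste0(mg, ".bias"), l2$db)
    d_h <- d_h + l2$dx
    dx <- d_h
    l1 <- layer_norm_bwd(
      attn_sublayer_bwd(G, d_h, cache$attn, model, li, boundaries, positions),
      cache$ln1, gn)
    acc_grad(G, paste0(ng, ".weight"), l1$dg)
    acc_grad(G, paste0(ng, ".bias"), l1$db)
    dx + l1$dx
  } else {
    # y = LN2(LN1(x + attn(x)) + ffn(LN1(...)))
    l2 <- layer_norm_bwd(dy, cache$ln2, gm)
    acc_grad(G, paste0(mg, ".weight"), l2$dg)
    acc_grad(G, paste0(mg, ".bias"), l2$db)
    d_ln1y <- l2$dx + ffn_sublayer_bwd(G, l2$dx, cache$ffn, model, li)
    l1 <- layer_norm_bwd(d_ln1y, cache$ln1, gn)
    acc_grad(G, paste0(ng, ".weight"), l1$dg)
    acc_grad(G, paste0(ng, ".bias"), l1$db)
    l1$dx + attn_sublayer_bwd(G, l1$dx, cache$attn, model, li, boundaries,
                              positions)
  }
}

# full backward pass; fwd must come from plm_forward(keep = TRUE). The seed
# gradient is either dlogits (through the LM head) or dhidden (directly on
# the final hidden states, e.g. from a pooled task head).
plm_backward <- function(model, fwd, dlogits = NULL, dhidden = NULL) {
  cfg <- model$config
  G <- new.env(parent = emptyenv())
  G$g <- list()
  G$W <- model$weights
  cache <- fwd$cache
  b <- cache$batch$boundaries

  if (!is.null(dlogits)) {
    hw <- if (cfg$tie_lm_head) model$weights$embed_tokens.weight else model$weights$lm_head.weight
    dx <- dlogits %*% hw
    head_g <- crossprod(dlogits, fwd$hidden)
    if (cfg$tie_lm_head) {
      acc_grad(G, "embed_tokens.weight", head_g)
    } else {
      acc_grad(G, "lm_head.weight", head_g)
    }
    acc_grad(G, "lm_head.bias", colSums(dlogits))
  } else {
    dx <- dhidden
  }

  for (li in rev(seq_len(cfg$num_layers))) {
    dx <- block_bwd(G, dx, cache$layers[[li]], model, li, b, cache$positions)
  }

  # embedding scatter: sum dx rows by token id / position row
  tok_g <- matrix(0, cfg$vocab_size, cfg$embed_dim)
  rs <- rowsum(dx, group = cache$tokens)
  tok_g[as.integer(rownames(rs)) + 1L, ] <- rs
  acc_grad(G, "embed_tokens.weight", tok_g)
  if (cfg$positional_mode == "learned") {
    pos_g <- matrix(0, nrow(model$weights$embed_positions.weight), cfg$embed_dim)
    ps <- rowsum(dx, group = cache$positions + POS_OFFSET)
    pos_g[as.integer(rownames(ps)) + 1L, ] <- ps
    acc_grad(G, "embed_positions.weight", pos_g)
  }
  G$g
}

# cross-entropy over selected rows of the logits; returns loss and dlogits
masked_ce <- function(logits, target_ids, rows) {
  sub <- logits[rows, , drop = FALSE]
  m <- apply(sub, 1L, max)
  lse <- m + log(rowSums(exp(sub - m)))
  logp <- sub - lse
  pick <- cbind(seq_along(rows), target_ids + 1L)
  loss <- -mean(logp[pick])
  P <- exp(logp)
  P[pick] <- P[pick] - 1
  dlogits <- matrix(0, nrow(logits), ncol(logits))
  dlogits[rows, ] <- P / length(rows)
  list(loss = loss, dlogits = dlogits)
}
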