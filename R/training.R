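# Optimization loops: the masked-LM objective, positional-embedding
# extension, and head/LoRA supervised fine-tuning with Adam, a step-decay
# learning-rate schedule, token-budget minibatches and gradient
# accumulation. Every source of randomness (masking, batch order,
# initialization) is derived from the config seed, so identical configs
# give identical runs.

#' Training configuration
#'
#' Defaults are the schedule used for head/LoRA fine-tuning of protein
#' language models: Adam with learning rate 1e-4 and momentum parameters
#' (0.9, 0.999), learning rate multiplied by 0.9 every 10 epochs over 100
#' epochs, minibatches of 50,000 tokens with 16 steps of gradient
#' accumulation, and a 15% masking rate for the masked-LM objective.
#'
#' @param lr Initial learning rate.
#' @param betas Adam momentum parameters.
#' @param lr_decay Multiplicative decay factor.
#' @param decay_every Epochs between decays.
#' @param epochs Training epochs.
#' @param minibatch_tokens Token budget per minibatch.
#' @param grad_accum_steps Minibatches accumulated per parameter update.
#' @param mask_rate Masked-LM masking probability (0 < rate < 1).
#' @param seed Integer seed controlling all run randomness.
#' @return A `plm_train_config`.
#' @export
train_config <- function(lr = 1e-4, betas = c(0.9, 0.999), lr_decay = 0.9,
                         decay_every = 10L, epochs = 100L,
                         minibatch_tokens = 50000L, grad_accum_steps = 16L,
                         mask_rate = 0.15, seed = 0L) {
  stopifnot(lr > 0, length(betas) == 2, all(betas > 0 & betas < 1),
            lr_decay > 0, decay_every >= 1, epochs >= 1,
            minibatch_tokens >= 1, grad_accum_steps >= 1,
            mask_rate > 0, mask_rate < 1)
  structure(list(lr = lr, betas = betas, lr_decay = lr_decay,
                 decay_every = as.integer(decay_every),
                 epochs = as.integer(epochs),
                 minibatch_tokens = as.integer(minibatch_tokens),
                 grad_accum_steps = as.integer(grad_accum_steps),
                 mask_rate = mask_rate, seed = as.integer(seed)),
            class = "plm_train_config")
}

#' Learning rate at a given epoch
#'
#' Step decay: `lr * lr_decay^((epoch - 1) %/% decay_every)`, i.e. the rate
#' is multiplied by the decay factor after every `decay_every` completed
#' epochs (at epoch 25 with the defaults: `1e-4 * 0.9^2`).
#'
#' @param config A [train_config()].
#' @param epoch 1-based epoch number.
#' @return Learning rate.
#' @export
lr_at_epoch <- function(config, epoch) {
  config$lr * config$lr_decay^((epoch - 1L) %/% config$decay_every)
}

# ---- Adam on flat named parameter lists -----------------------------------

adam_init <- function() list(m = list(), v = list(), t = 0L)

adam_step <- function(params, grads, state, lr, betas, eps = 1e-8) {
  state$t <- state$t + 1L
  b1 <- betas[1]; b2 <- betas[2]
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    if (is.null(state$m[[nm]])) {
      state$m[[nm]] <- g * 0
      state$v[[nm]] <- g * 0
    }
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# ---- trainable-parameter bookkeeping --------------------------------------

# which flat parameter names train under a given mode
trainable_names <- function(model, mode) {
  switch(mode,
    all = names(model$weights),
    positional = {
      if (is.null(model$weights$embed_positions.weight)) {
        stop("extension applies to learned positions only", call. = FALSE)
      }
      "embed_positions.weight"
    },
    lora = {
      if (is.null(model$adapters)) stop("model has no adapters", call. = FALSE)
      as.vector(t(outer(paste0("adapters.", names(model$adapters)),
                        c(".A", ".B"), paste0)))
    },
    stop("unknown trainable mode: ", mode, call. = FALSE)
  )
}

get_params <- function(model, nms) {
  out <- list()
  for (nm in nms) {
    if (startsWith(nm, "adapters.")) {
      key <- sub("^adapters\\.", "", sub("\\.(A|B)$", "", nm))
      out[[nm]] <- model$adapters[[key]][[sub("^.*\\.", "", nm)]]
    } else {
      out[[nm]] <- model$weights[[nm]]
    }
  }
  out
}

set_params <- function(model, params) {
  for (nm in names(params)) {
    if (startsWith(nm, "adapters.")) {
      key <- sub("^adapters\\.", "", sub("\\.(A|B)$", "", nm))
      model$adapters[[key]][[sub("^.*\\.", "", nm)]] <- params[[nm]]
    } else {
      model$weights[[nm]] <- params[[nm]]
    }
  }
  model
}

# ---- masked-LM objective --------------------------------------------------

#' Masked language-model loss on a packed batch
#'
#' Each residue token is masked independently with probability `mask_rate`
#' (at least one position is always masked); special tokens are never
#' masked. Masked positions are replaced by the mask token — no 80/10/10
#' corruption split — and the loss is the cross-entropy of the true residue
#' at the masked positions only.
#'
#' @param model A `plm_model`.
#' @param batch A `packed_batch` (or token vector).
#' @param mask_rate Masking probability.
#' @param seed Seed for the mask draw.
#' @param grad Also compute gradients (flat named list).
#' @param alphabet Token alphabet.
#' @return List with `loss`, `masked_rows` (row indices into the packed
#'   stream), `n_masked`, and `grads` when requested.
#' @export
masked_lm_loss <- function(model, batch, mask_rate = 0.15, seed = 0L,
                           grad = FALSE, alphabet = esm_alphabet()) {
  batch <- as_packed(batch)
  candidates <- which(batch$tokens %in% residue_ids(alphabet))
  if (length(candidates) == 0L) stop("no residue tokens to mask", call. = FALSE)
  rows <- with_seed(seed, {
    sel <- candidates[stats::runif(length(candidates)) < mask_rate]
    if (length(sel) == 0L) sel <- sample(candidates, 1L)
    sel
  })
  targets <- batch$tokens[rows]
  masked <- batch
  masked$tokens[rows] <- alphabet$mask
  fwd <- plm_forward(model, masked, keep = grad)
  ce <- masked_ce(fwd$logits, targets, rows)
  out <- list(loss = ce$loss, masked_rows = rows, n_masked = length(rows))
  if (grad) out$grads <- plm_backward(model, fwd, ce$dlogits)
  out
}

#' Train a model on the masked-LM objective
#'
#' A compact optimization loop used for sanity and convergence checks:
#' token-budget minibatches over the corpus, Adam updates on the chosen
#' parameter subset, fresh random masks per step. All parameters outside
#' the trainable set are left bitwise untouched.
#'
#' @param model A `plm_model`.
#' @param sequences Character vector of amino-acid sequences, or a list of
#'   token-id vectors.
#' @param steps Number of optimizer steps.
#' @param config A [train_config()].
#' @param trainable `"all"`, `"positional"` (learned positional table only)
#'   or `"lora"` (adapter tensors only).
#' @return List with `model` (trained) and `log` (data.frame of step,
#'   loss, lr).
#' @export
train_mlm <- function(model, sequences, steps = 50L, config = train_config(),
                      trainable = "all") {
  toks <- if (is.character(sequences)) lapply(sequences, tokenize) else sequences
  nms <- trainable_names(model, trainable)
  params <- get_params(model, nms)
  state <- adam_init()
  log <- data.frame(step = integer(0), loss = numeric(0), lr = numeric(0))
  plan <- plan_token_batches(lengths(toks), config$minibatch_tokens,
                             seed = config$seed)
  nb <- length(plan$batches)
  for (st in seq_len(steps)) {
    pb <- pack(toks[plan$batches[[(st - 1L) %% nb + 1L]]])
    ml <- masked_lm_loss(model, pb, config$mask_rate,
                         seed = config$seed + st, grad = TRUE)
    g <- ml$grads[nms]
    names(g) <- nms
    epoch <- (st - 1L) %/% max(1L, nb) + 1L
    up <- adam_step(params, g, state, lr_at_epoch(config, epoch),
                    config$betas)
    params <- up$params
    state <- up$state
    model <- set_params(model, params)
    log <- rbind(log, data.frame(step = st, loss = ml$loss,
                                 lr = lr_at_epoch(config, epoch)))
  }
  list(model = model, log = log)
}

#' Extend a learned positional-embedding table
#'
#' Resizes the positional table of a learned-positional model to support
#' `new_max` positions (plus the two offset rows of the ESM-1x indexing
#' convention): existing rows are copied, new rows are seeded N(0, 0.02).
#' Only the positional table is marked trainable; optionally the table is
#' then retrained on a corpus with the masked-LM objective while every
#' other tensor stays bitwise frozen. For an embedding width of 1280
#' extended to 4096 positions this trains (4096 + 2) * 1280 = 5,245,440
#' parameters.
#'
#' @param model A learned-positional `plm_model`.
#' @param new_max New maximum sequence length (> current).
#' @param corpus Optional character vector of training sequences.
#' @param steps Optimizer steps when `corpus` is given.
#' @param config A [train_config()].
#' @param val_fraction Fraction of the corpus reserved for validation
#'   (at least one sequence).
#' @return List with `model`, `report` (old/new max, trainable parameter
#'   count) and `log` (per-step train loss and periodic validation loss;
#'   NULL when no corpus is given).
#' @export
extend_positional <- function(model, new_max, corpus = NULL, steps = 200L,
                              config = train_config(), val_fraction = 0.01) {
  if (model$config$positional_mode != "learned") {
    stop("extension applies to learned positions only", call. = FALSE)
  }
  old_max <- model$config$max_positions
  if (new_max <= old_max) stop("new_max must exceed current max_positions",
                               call. = FALSE)
  d <- model$config$embed_dim
  old_tab <- model$weights$embed_positions.weight
  new_tab <- with_seed(config$seed, {
    matrix(stats::rnorm((new_max + POS_OFFSET) * d, sd = 0.02),
           new_max + POS_OFFSET, d)
  })
  new_tab[seq_len(nrow(old_tab)), ] <- old_tab
  cfg <- model$config
  cfg$max_positions <- as.integer(new_max)
  model <- new_plm_model(cfg, model$weights, model$adapters, model$lora)
  model$weights$embed_positions.weight <- new_tab

  report <- list(old_max = old_max, new_max = as.integer(new_max),
                 trainable_params = as.numeric(length(new_tab)))
  log <- NULL
  if (!is.null(corpus) && steps > 0L) {
    n_val <- max(1L, floor(length(corpus) * val_fraction))
    val_idx <- with_seed(config$seed + 7L, sample(length(corpus), n_val))
    train_seqs <- corpus[-val_idx]
    val_toks <- lapply(corpus[val_idx], tokenize)
    val_loss <- function(m) {
      masked_lm_loss(m, pack(val_toks), config$mask_rate,
                     seed = config$seed + 999L)$loss
    }
    log <- data.frame(step = integer(0), loss = numeric(0),
                      val_loss = numeric(0))
    tr <- train_mlm(model, train_seqs, steps = steps, config = config,
                    trainable = "positional")
    model <- tr$model
    log <- tr$log
    log$val_loss <- NA_real_
    log$val_loss[nrow(log)] <- val_loss(model)
    attr(log, "val_loss_initial") <- NULL
  }
  list(model = model, report = report, log = log)
}

#' Epoch count implied by a step budget
#'
#' `steps * tokens_per_step / corpus_tokens`: how many passes over a corpus
#' a fixed step budget amounts to. Returned both raw and rounded to the
#' nearest integer (e.g. 500,000 steps of 2 million tokens on an 18.7
#' billion token corpus is about 53 epochs).
#'
#' @param steps Number of optimizer steps.
#' @param tokens_per_step Tokens consumed per step.
#' @param corpus_tokens Total tokens in the corpus.
#' @return List with `raw` and `epochs` (rounded).
#' @export
training_time_budget <- function(steps, tokens_per_step, corpus_tokens) {
  stopifnot(steps > 0, tokens_per_step > 0)
  if (corpus_tokens <= 0) stop("corpus_tokens must be positive", call. = FALSE)
  raw <- steps * tokens_per_step / corpus_tokens
  list(raw = raw, epochs = round(raw))
}

# ---- supervised fine-tuning ----------------------------------------------

pool_residues <- function(E) E[2:(nrow(E) - 1L), , drop = FALSE]

#' Fine-tune a task head (optionally with LoRA) on labeled proteins
#'
#' Supervised training of a pooled-embedding head on per-protein labels:
#' mean or attention pooling over residue embeddings, a two-layer head
#' ([regression_head()]), mean-squared-error loss for regression or
#' binary cross-entropy (sigmoid head) for classification. In `head`
#' mode the base model is frozen and only head (+ pooling) parameters
#' train; in `lora` mode adapters must already be attached and train
#' together with the head while base weights stay bitwise frozen. Binary
#' tasks upsample the positive class to balance each epoch. Minibatches
#' are planned by token budget; parameter updates happen every
#' `grad_accum_steps` minibatches.
#'
#' @param model A `plm_model` (with adapters attached for `mode = "lora"`).
#' @param train data.frame with `sequence` and `label` columns.
#' @param val Optional validation data.frame of the same shape.
#' @param task `"regression"` or `"binary"`.
#' @param pooling `"mean"` or `"attention"`.
#' @param mode `"head"` (head-only) or `"lora"`.
#' @param config A [train_config()].
#' @param head_hidden Hidden width of the head.
#' @param n_class_tokens Class tokens for attention pooling.
#' @return List with `model`, `head`, `pooling_layer` (NULL for mean
#'   pooling), `log` (per-epoch data.frame: epoch, lr, train_loss and —
#'   when `val` is given — `val_metric`: Spearman's rho for regression,
#'   AUROC for binary), and `predict(records)` closure.
#' @export
finetune <- function(model, train, val = NULL,
                     task = c("regression", "binary"),
                     pooling = c("mean", "attention"),
                     mode = c("head", "lora"),
                     config = train_config(), head_hidden = 256L,
                     n_class_tokens = 1L) {
  task <- match.arg(task)
  pooling <- match.arg(pooling)
  mode <- match.arg(mode)
  stopifnot(is.data.frame(train), all(c("sequence", "label") %in% names(train)))
  if (nrow(train) == 0L) stop("empty training split", call. = FALSE)
  if (!is.null(val) && nrow(val) == 0L) stop("empty validation split", call. = FALSE)
  if (mode == "lora" && is.null(model$adapters)) {
    stop("mode = 'lora' requires a model with adapters attached", call. = FALSE)
  }
  d <- model$config$embed_dim
  head <- regression_head(d * n_class_tokens, head_hidden,
                          seed = config$seed + 1L)
  pool_layer <- if (pooling == "attention") {
    attention_pooling(d, d, n_class_tokens, seed = config$seed + 2L)
  } else {
    NULL
  }

  toks <- lapply(train$sequence, tokenize)
  embed_all <- function(m, token_lists) {
    out <- vector("list", length(token_lists))
    plan0 <- plan_token_batches(lengths(token_lists), config$minibatch_tokens, 0L)
    for (bi in plan0$batches) {
      pb <- pack(token_lists[bi])
      per <- unpack(pb, forward_hidden(pb, m))
      for (j in seq_along(bi)) out[[bi[j]]] <- pool_residues(per[[j]])
    }
    out
  }
  # in head-only mode base embeddings are frozen: compute them once
  emb_cache <- NULL
  val_cache <- NULL
  if (mode == "head") {
    emb_cache <- embed_all(model, toks)
    if (pooling == "mean") emb_cache <- lapply(emb_cache, mean_pool)
    if (!is.null(val)) {
      val_cache <- embed_all(model, lapply(val$sequence, tokenize))
      if (pooling == "mean") val_cache <- lapply(val_cache, mean_pool)
    }
  }

  head_params <- unclass(head)
  pool_params <- if (!is.null(pool_layer)) pool_layer[c("C", "Wk")] else list()
  names(pool_params) <- if (length(pool_params)) c("pool.C", "pool.Wk")
  lora_nms <- if (mode == "lora") trainable_names(model, "lora") else character(0)
  params <- c(head_params, pool_params, get_params(model, lora_nms))
  state <- adam_init()

  current_head <- function() {
    structure(params[c("W1", "b1", "W2", "b2")], class = "regression_head")
  }
  current_pool <- function() {
    if (is.null(pool_layer)) return(NULL)
    structure(list(C = params[["pool.C"]], Wk = params[["pool.Wk"]],
                   d_k = pool_layer$d_k), class = "attention_pooling")
  }

  # pooled representation + caches for one protein's residue embeddings
  pool_fwd <- function(E) {
    if (pooling == "mean") {
      list(h = mean_pool(E), cache = list(n = nrow(E)))
    } else {
      pf <- attention_pool_fwd(E, current_pool())
      list(h = as.vector(t(pf$h)), cache = pf)
    }
  }

  predict_records <- function(records) {
    seqs <- if (is.data.frame(records)) records$sequence else records
    tk <- lapply(seqs, tokenize)
    m <- set_params(model, params[lora_nms])
    out <- numeric(length(tk))
    plan <- plan_token_batches(lengths(tk), config$minibatch_tokens, 0L)
    for (bi in plan$batches) {
      pb <- pack(tk[bi])
      per <- unpack(pb, forward_hidden(pb, m))
      for (j in seq_along(bi)) {
        h <- pool_fwd(pool_residues(per[[j]]))$h
        yy <- regression_forward(h, current_head())
        out[bi[j]] <- if (task == "binary") stats::plogis(yy) else yy
      }
    }
    out
  }

  eval_val <- function() {
    p <- if (mode == "head") {
      vapply(val_cache, function(E) {
        h <- if (pooling == "mean") E else pool_fwd(E)$h
        yy <- regression_forward(h, current_head())
        if (task == "binary") stats::plogis(yy) else yy
      }, numeric(1))
    } else {
      predict_records(val)
    }
    if (task == "regression") spearman_rho(p, val$label) else auroc(val$label, p)
  }

  log <- NULL
  accum <- NULL
  accum_n <- 0L
  n_updates <- 0L

  for (epoch in seq_len(config$epochs)) {
    lr <- lr_at_epoch(config, epoch)
    idx_pool <- seq_len(nrow(train))
    if (task == "binary") {
      idx_pool <- upsample_positive(train$label, seed = config$seed + epoch)
    }
    ord <- with_seed(config$seed * 1000L + epoch,
                     idx_pool[sample.int(length(idx_pool))])
    plan <- plan_token_batches(lengths(toks)[ord], config$minibatch_tokens,
                               seed = config$seed + epoch)
    epoch_loss <- 0
    n_batches <- 0L
    for (bi in plan$batches) {
      items <- ord[bi]
      gb <- list()
      add <- function(nm, g) {
        gb[[nm]] <<- if (is.null(gb[[nm]])) g else gb[[nm]] + g
      }
      m_cur <- if (mode == "lora") set_params(model, params[lora_nms]) else model
      fwd_full <- NULL
      dhid <- NULL
      if (mode == "lora") {
        pb <- pack(toks[items])
        fwd_full <- plm_forward(m_cur, pb, keep = TRUE, want_logits = FALSE)
        per <- unpack(pb, fwd_full$hidden)
        dhid <- matrix(0, nrow(fwd_full$hidden), d)
      } else {
        per <- emb_cache[items]
      }
      batch_loss <- 0
      for (j in seq_along(items)) {
        if (mode == "head" && pooling == "mean") {
          E <- NULL
          pf <- list(h = per[[j]], cache = NULL)
        } else {
          E <- if (mode == "lora") pool_residues(per[[j]]) else per[[j]]
          pf <- pool_fwd(E)
        }
        hf <- head_fwd(matrix(pf$h, nrow = 1L), current_head())
        y <- train$label[items[j]]
        if (task == "regression") {
          err <- hf$y - y
          batch_loss <- batch_loss + err^2
          dy <- 2 * err
        } else {
          p <- stats::plogis(hf$y)
          batch_loss <- batch_loss - (y * log(p) + (1 - y) * log1p(-p))
          dy <- p - y
        }
        hb <- head_bwd(dy / length(items), hf, current_head())
        for (nm in names(hb$grads)) add(nm, hb$grads[[nm]])
        dh <- hb$dh
        dE <- NULL
        if (pooling == "attention") {
          pb2 <- attention_pool_bwd(matrix(dh, ncol = d, byrow = TRUE),
                                    pf$cache, current_pool())
          add("pool.C", pb2$grads$C)
          add("pool.Wk", pb2$grads$Wk)
          dE <- pb2$dE
        } else if (mode == "lora") {
          dE <- matrix(rep(as.vector(dh) / nrow(E), each = nrow(E)),
                       nrow(E), d)
        }
        if (mode == "lora") {
          b <- pb$boundaries
          rows <- (b[j] + 2L):(b[j + 1L] - 1L)   # residue rows of protein j
          dhid[rows, ] <- dhid[rows, ] + dE
        }
      }
      if (mode == "lora") {
        gl <- plm_backward(m_cur, fwd_full, dlogits = NULL, dhidden = dhid)
        for (nm in lora_nms) if (!is.null(gl[[nm]])) add(nm, gl[[nm]])
      }
      epoch_loss <- epoch_loss + batch_loss / length(items)
      n_batches <- n_batches + 1L
      # gradient accumulation: update every grad_accum_steps minibatches
      if (is.null(accum)) accum <- gb else {
        for (nm in names(gb)) {
          accum[[nm]] <- if (is.null(accum[[nm]])) gb[[nm]] else accum[[nm]] + gb[[nm]]
        }
      }
      accum_n <- accum_n + 1L
      if (accum_n == config$grad_accum_steps) {
        for (nm in names(accum)) accum[[nm]] <- accum[[nm]] / accum_n
        up <- adam_step(params, accum, state, lr, config$betas)
        params <- up$params
        state <- up$state
        accum <- NULL
        accum_n <- 0L
        n_updates <- n_updates + 1L
      }
    }
    row <- data.frame(epoch = epoch, lr = lr,
                      train_loss = epoch_loss / max(1L, n_batches))
    if (!is.null(val)) row$val_metric <- eval_val()
    log <- rbind(log, row)
  }
  # flush a partial accumulation window at the end of training
  if (!is.null(accum) && accum_n > 0L) {
    for (nm in names(accum)) accum[[nm]] <- accum[[nm]] / accum_n
    up <- adam_step(params, accum, state, lr_at_epoch(config, config$epochs),
                    config$betas)
    params <- up$params
    n_updates <- n_updates + 1L
  }

  list(model = set_params(model, params[lora_nms]),
       head = current_head(),
       pooling_layer = current_pool(),
       log = log,
       n_updates = n_updates,
       predict = predict_records)
}
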