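# Model-quality and variant-effect scoring. Pseudo-perplexity masks each
# residue in turn and averages the negative log-probability of the true
# residue; the masked-marginal variant score compares the log-probabilities
# of the alternative and reference residues at a masked position. All
# masked copies of a sequence are evaluated through sequence packing, so
# scoring exercises the same batched code path as inference.

logsoftmax_row <- function(x) {
  m <- max(x)
  x - (m + log(sum(exp(x - m))))
}

#' Log-probabilities at a masked position
#'
#' Replaces one residue with the mask token, runs the model once and
#' returns the log-softmax over the vocabulary at that position (natural
#' log). This is the primitive behind both pseudo-perplexity and the
#' masked-marginal variant score.
#'
#' @param model A `plm_model`.
#' @param sequence Amino-acid string.
#' @param position 1-based residue position to mask.
#' @param alphabet Token alphabet.
#' @return Named numeric vector of length `vocab_size` (names are token
#'   symbols), summing to 1 after `exp()`.
#' @export
masked_logprobs <- function(model, sequence, position,
                            alphabet = esm_alphabet()) {
  toks <- tokenize(sequence, alphabet)
  n_res <- length(toks) - 2L
  if (position < 1L || position > n_res) {
    stop(sprintf("position %d outside sequence of length %d", position, n_res),
         call. = FALSE)
  }
  toks[position + 1L] <- alphabet$mask
  logits <- forward_logits(toks, model)
  stats::setNames(logsoftmax_row(logits[position + 1L, ]), alphabet$symbols)
}

#' Pseudo-perplexity of a sequence under a model
#'
#' Masks each residue position separately (special tokens are never masked
#' and never enter the average), estimates the probability of the true
#' residue from the masked forward pass, and exponentiates the mean
#' negative log-probability:
#' `exp( (1/T) * sum_t -log p(x_t | x_{\\t}) )`.
#' A model emitting uniform logits scores exactly the vocabulary size; a
#' perfect model scores 1. The T masked copies are evaluated in packed
#' batches under `max_tokens`; the result is invariant to the batch plan.
#'
#' @param model A `plm_model`.
#' @param sequence Amino-acid string.
#' @param max_tokens Token budget per packed batch.
#' @param alphabet Token alphabet.
#' @return Pseudo-perplexity, a real number >= 1 (up to float tolerance).
#' @export
pseudo_perplexity <- function(model, sequence, max_tokens = 4096L,
                              alphabet = esm_alphabet()) {
  toks <- tokenize(sequence, alphabet)
  T_ <- length(toks) - 2L
  copies <- lapply(seq_len(T_), function(t) {
    ct <- toks
    ct[t + 1L] <- alphabet$mask
    ct
  })
  plan <- plan_token_batches(lengths(copies), max_tokens, seed = 0L)
  nll <- numeric(T_)
  for (bi in plan$batches) {
    pb <- pack(copies[bi])
    logits <- forward_logits(pb, model)
    b <- pb$boundaries
    for (j in seq_along(bi)) {
      t <- bi[j]
      row <- b[j] + t + 1L       # masked position inside copy t
      lp <- logsoftmax_row(logits[row, ])
      nll[t] <- -lp[toks[t + 1L] + 1L]
    }
  }
  exp(mean(nll))
}

#' Specify a missense variant
#'
#' @param protein_id Protein identifier.
#' @param position 1-based residue position.
#' @param ref Reference amino acid (must match the sequence; checked at
#'   scoring time).
#' @param alt Alternative amino acid.
#' @return A one-row data.frame (a `VariantSpec`).
#' @export
variant_spec <- function(protein_id, position, ref, alt) {
  stopifnot(position >= 1, nchar(ref) == 1L, nchar(alt) == 1L)
  data.frame(protein_id = protein_id, position = as.integer(position),
             ref = toupper(ref), alt = toupper(alt),
             stringsAsFactors = FALSE)
}

check_ref <- function(sequence, position, ref, protein_id = "?") {
  n <- nchar(sequence)
  if (position < 1L || position > n) {
    stop(sprintf("variant position %d outside %s (length %d)", position,
                 protein_id, n), call. = FALSE)
  }
  obs <- toupper(substr(sequence, position, position))
  if (obs != toupper(ref)) {
    stop(sprintf(
      "reference mismatch for %s at position %d: expected %s, sequence has %s",
      protein_id, position, ref, obs), call. = FALSE)
  }
  invisible(TRUE)
}

#' Masked-marginal variant effect score
#'
#' Masks the variant position, runs the model once, and scores the
#' substitution as `v = log p(alt) - log p(ref)` from the masked position's
#' log-softmax (natural log). Negative scores mean the model disfavors the
#' substitution; `v = 0` exactly when `alt == ref`.
#'
#' @param model A `plm_model`.
#' @param sequence Amino-acid string containing the variant.
#' @param variant A [variant_spec()] row.
#' @param alphabet Token alphabet.
#' @return One-row data.frame: `protein_id`, `position`, `ref`, `alt`,
#'   `score` (nats).
#' @export
masked_margin <- function(model, sequence, variant,
                          alphabet = esm_alphabet()) {
  check_ref(sequence, variant$position, variant$ref, variant$protein_id)
  lp <- masked_logprobs(model, sequence, variant$position, alphabet)
  ref_id <- alphabet$aa_ids[[toupper(variant$ref)]]
  alt_id <- alphabet$aa_ids[[toupper(variant$alt)]]
  data.frame(variant[c("protein_id", "position", "ref", "alt")],
             score = unname(lp[alt_id + 1L] - lp[ref_id + 1L]),
             stringsAsFactors = FALSE)
}

#' Center a window on a variant in a long sequence
#'
#' Returns a contiguous slice of at most `window` residues containing
#' `position` as close to the center as clipping at the sequence ends
#' allows, plus the position re-indexed into the slice. When both flanks
#' overflow, the new position is `window %/% 2` (ties broken toward the
#' left flank). Sequences no longer than `window` are returned unchanged.
#'
#' @param sequence Amino-acid string.
#' @param position 1-based residue position.
#' @param window Maximum slice length (>= 1).
#' @return List with `sequence`, `position`, `offset` (0-based start of the
#'   slice in the original sequence).
#' @export
truncate_center <- function(sequence, position, window) {
  stopifnot(window >= 1)
  window <- as.integer(window)
  position <- as.integer(position)
  n <- nchar(sequence)
  if (position < 1L || position > n) {
    stop("position outside sequence", call. = FALSE)
  }
  if (n <= window) {
    return(list(sequence = sequence, position = as.integer(position),
                offset = 0L))
  }
  start <- position - (window %/% 2L) + 1L
  start <- max(1L, min(start, n - window + 1L))
  list(sequence = substr(sequence, start, start + window - 1L),
       position = as.integer(position - start + 1L),
       offset = start - 1L)
}

#' Score a table of variants in packed batches
#'
#' Applies [masked_margin()] to every row of a variant table, batching all
#' masked forward passes under a token budget via sequence packing. Output
#' order matches input order, duplicates score identically, and the scores
#' do not depend on the batch plan. Sequences longer than the model's
#' supported length (learned-positional mode) or an explicit `window` are
#' truncated around the variant with [truncate_center()].
#'
#' @param model A `plm_model`.
#' @param records data.frame with `id`, `sequence` (e.g. from
#'   [read_fasta()]).
#' @param variants data.frame with `protein_id`, `position`, `ref`, `alt`.
#' @param max_tokens Token budget per packed batch.
#' @param window Truncation window in residues, or NULL to truncate only
#'   when the model's positional capacity forces it.
#' @param alphabet Token alphabet.
#' @return data.frame: input columns plus `score` (nats).
#' @export
score_variant_table <- function(model, records, variants,
                                max_tokens = 4096L, window = NULL,
                                alphabet = esm_alphabet()) {
  stopifnot(is.data.frame(variants))
  if (nrow(variants) == 0L) {
    return(cbind(variants, score = numeric(0)))
  }
  missing <- setdiff(unique(variants$protein_id), records$id)
  if (length(missing) > 0L) {
    stop("variant protein(s) not in FASTA: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  seqs <- stats::setNames(records$sequence, records$id)

  cap <- if (model$config$positional_mode == "learned") {
    model$config$max_positions - 2L
  } else {
    Inf
  }
  eff_window <- min(cap, if (is.null(window)) Inf else window)

  prep <- lapply(seq_len(nrow(variants)), function(i) {
    v <- variants[i, ]
    s <- seqs[[v$protein_id]]
    check_ref(s, v$position, v$ref, v$protein_id)
    if (is.finite(eff_window) && nchar(s) > eff_window) {
      tc <- truncate_center(s, v$position, eff_window)
      s <- tc$sequence
      v$position_eff <- tc$position
    } else {
      v$position_eff <- v$position
    }
    toks <- tokenize(s, alphabet)
    toks[v$position_eff + 1L] <- alphabet$mask
    list(v = v, toks = toks)
  })

  toklists <- lapply(prep, `[[`, "toks")
  plan <- plan_token_batches(lengths(toklists), max_tokens, seed = 0L)
  score <- numeric(nrow(variants))
  for (bi in plan$batches) {
    pb <- pack(toklists[bi])
    logits <- forward_logits(pb, model)
    b <- pb$boundaries
    for (j in seq_along(bi)) {
      i <- bi[j]
      v <- prep[[i]]$v
      row <- b[j] + v$position_eff + 1L
      lp <- logsoftmax_row(logits[row, ])
      ref_id <- alphabet$aa_ids[[toupper(v$ref)]]
      alt_id <- alphabet$aa_ids[[toupper(v$alt)]]
      score[i] <- lp[alt_id + 1L] - lp[ref_id + 1L]
    }
  }
  cbind(variants, score = score)
}

#' Rank and classification metrics
#'
#' `spearman_rho` is Spearman's rank correlation; `auroc` is the area under
#' the ROC curve computed as the Mann-Whitney rank statistic; `auprc` is
#' the area under the precision-recall curve by step-wise integration.
#'
#' @param x,y Numeric vectors (for `spearman_rho`).
#' @param labels Binary ground-truth vector.
#' @param scores Predicted scores, higher = more positive.
#' @return A number in `[-1, 1]` (`spearman_rho`) or `[0, 1]` (others).
#' @export
spearman_rho <- function(x, y) {
  stats::cor(x, y, method = "spearman")
}

#' @rdname spearman_rho
#' @export
auroc <- function(labels, scores) {
  y <- as.integer(labels)
  stopifnot(all(y %in% c(0L, 1L)))
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L) stop("both classes required", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' @rdname spearman_rho
#' @export
auprc <- function(labels, scores) {
  y <- as.integer(labels)[order(scores, decreasing = TRUE)]
  tp <- cumsum(y)
  precision <- tp / seq_along(y)
  recall <- tp / sum(y)
  sum(precision[y == 1L]) / sum(y)   # average precision
}
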