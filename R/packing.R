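#' Pack token sequences into one padding-free stream
#'
#' Sequence packing concatenates variable-length token sequences into a
#' single flat stream with boundary bookkeeping, instead of padding every
#' sequence to the longest one. Attention is later restricted to within-
#' sequence pairs by [block_diagonal_mask()], so a packed forward pass is
#' mathematically identical to running each sequence alone.
#'
#' @param sequences List of non-empty integer token-id vectors.
#' @return A `packed_batch`: list with `tokens` (flat integer vector),
#'   `boundaries` (cumulative start offsets, length `n_sequences + 1`,
#'   starting at 0) and `max_seqlen`.
#' @examples
#' pb <- pack(list(1:3, 4:8, 9:10))
#' pb$boundaries   # 0 3 8 10
#' @export
pack <- function(sequences) {
  if (!is.list(sequences) || length(sequences) == 0L) {
    stop("'sequences' must be a non-empty list of token vectors", call. = FALSE)
  }
  lens <- lengths(sequences)
  if (any(lens == 0L)) {
    stop("packed sequences must be non-empty (member ",
         paste(which(lens == 0L), collapse = ", "), ")", call. = FALSE)
  }
  structure(
    list(
      tokens = as.integer(unlist(sequences, use.names = FALSE)),
      boundaries = c(0L, cumsum(as.integer(lens))),
      max_seqlen = max(lens)
    ),
    class = "packed_batch"
  )
}

#' @export
print.packed_batch <- function(x, ...) {
  cat(sprintf("<packed_batch> %d sequences, %d tokens, max len %d\n",
              n_sequences(x), length(x$tokens), x$max_seqlen))
  invisible(x)
}

#' @rdname pack
#' @param batch A `packed_batch`.
#' @export
n_sequences <- function(batch) length(batch$boundaries) - 1L

#' Slice per-token values back into per-sequence pieces
#'
#' @param batch A `packed_batch`.
#' @param values A vector or matrix with one entry/row per packed token; if
#'   missing, the token ids themselves are unpacked.
#' @return List with one element per sequence, in packing order.
#' @export
unpack <- function(batch, values = NULL) {
  stopifnot(inherits(batch, "packed_batch"))
  if (is.null(values)) values <- batch$tokens
  n_tok <- length(batch$tokens)
  rows <- if (is.matrix(values)) nrow(values) else length(values)
  if (rows != n_tok) {
    stop(sprintf("values have %d rows but batch has %d tokens", rows, n_tok),
         call. = FALSE)
  }
  b <- batch$boundaries
  lapply(seq_len(n_sequences(batch)), function(i) {
    idx <- (b[i] + 1L):b[i + 1L]
    if (is.matrix(values)) values[idx, , drop = FALSE] else values[idx]
  })
}

#' Block-diagonal attention mask for a packed batch
#'
#' Tokens may attend only within their own sequence: entry `(i, j)` is TRUE
#' iff tokens `i` and `j` fall between the same pair of boundaries. This
#' dense mask is the reference semantics that variable-length attention
#' kernels implement implicitly.
#'
#' @param boundaries Cumulative offsets as in a `packed_batch`, or the
#'   `packed_batch` itself.
#' @return Logical `n_tokens x n_tokens` matrix of allowed pairs.
#' @export
block_diagonal_mask <- function(boundaries) {
  if (inherits(boundaries, "packed_batch")) boundaries <- boundaries$boundaries
  stopifnot(length(boundaries) >= 2, boundaries[1] == 0,
            all(diff(boundaries) > 0))
  n <- boundaries[length(boundaries)]
  seq_id <- sequence_ids(boundaries)
  outer(seq_id, seq_id, `==`)
}

# per-token sequence index (1-based) from boundary offsets
sequence_ids <- function(boundaries) {
  if (inherits(boundaries, "packed_batch")) boundaries <- boundaries$boundaries
  rep.int(seq_len(length(boundaries) - 1L), diff(boundaries))
}

# per-token 0-based position, restarting at every sequence boundary
packed_positions <- function(boundaries) {
  if (inherits(boundaries, "packed_batch")) boundaries <- boundaries$boundaries
  unlist(lapply(diff(boundaries), function(l) seq_len(l) - 1L),
         use.names = FALSE)
}

#' Plan batches under a token budget
#'
#' Builds batches whose summed token counts stay below a budget, so that
#' every optimization or inference step does a comparable amount of work
#' regardless of how long individual proteins are. Sequences are sorted by
#' length (longest first) and placed greedily into the first batch with
#' room; batch order is then shuffled deterministically with `seed`. A
#' sequence longer than the budget gets a singleton batch and is flagged in
#' the report.
#'
#' @param lengths Positive integer token counts, one per sequence.
#' @param max_tokens Token budget per batch.
#' @param seed Integer seed for the batch-order shuffle.
#' @return A `batch_plan`: list with `batches` (list of integer index
#'   vectors into `lengths`), `max_tokens`, and `report` (data.frame with
#'   per-batch `n_sequences`, `n_tokens`, `utilization`, `oversized`).
#' @export
plan_token_batches <- function(lengths, max_tokens, seed = 0L) {
  stopifnot(length(lengths) >= 1, all(lengths >= 1), max_tokens >= 1)
  lengths <- as.integer(lengths)
  ord <- order(lengths, decreasing = TRUE)

  batch_idx <- list()
  batch_tok <- integer(0)
  for (i in ord) {
    fit <- which(batch_tok + lengths[i] <= max_tokens)
    if (length(fit) > 0L) {
      j <- fit[1L]
      batch_idx[[j]] <- c(batch_idx[[j]], i)
      batch_tok[j] <- batch_tok[j] + lengths[i]
    } else {
      batch_idx[[length(batch_idx) + 1L]] <- i
      batch_tok <- c(batch_tok, lengths[i])
    }
  }

  perm <- with_seed(seed, sample.int(length(batch_idx)))
  batch_idx <- batch_idx[perm]
  batch_tok <- batch_tok[perm]

  report <- data.frame(
    batch = seq_along(batch_idx),
    n_sequences = lengths(batch_idx),
    n_tokens = batch_tok,
    utilization = batch_tok / max_tokens,
    oversized = batch_tok > max_tokens
  )
  structure(
    list(batches = batch_idx, max_tokens = as.integer(max_tokens),
         report = report),
    class = "batch_plan"
  )
}

#' @export
print.batch_plan <- function(x, ...) {
  cat(sprintf(
    "<batch_plan> %d batches, budget %d tokens, mean utilization %.2f\n",
    length(x$batches), x$max_tokens, mean(x$report$utilization)))
  invisible(x)
}

# evaluate `expr` under a temporary RNG seed, restoring global RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
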