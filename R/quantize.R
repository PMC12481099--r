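# Blockwise weight quantization for inference-side compression.
#
# absmax int8: per block, codes = round(w / absmax * 127), stored with one
# float constant per block. NF4: per block, w / absmax is snapped to the
# nearest of 16 normal-quantile codebook levels and stored as a 4-bit index.
# Double quantization compresses the per-block constants themselves; outlier
# decomposition holds rare large-magnitude columns out of the quantized part
# so they cannot distort the block scales.

#' The NF4 codebook
#'
#' 16 levels built from quantiles of the standard normal, normalized to
#' `[-1, 1]`: 8 positive quantiles, 7 negative quantiles and an exact 0 —
#' the NormalFloat construction, which allocates levels where normally
#' distributed weights actually fall. The codebook is sorted, spans exactly
#' `[-1, 1]` and contains 0, so all-zero blocks are represented exactly.
#'
#' @return Sorted numeric vector of length 16.
#' @export
nf4_codebook <- function() {
  offset <- 0.5 * (1 / 32 + 1 / 30)
  pos <- stats::qnorm(seq(offset, 0.5, length.out = 9))[1:8]
  neg <- -stats::qnorm(seq(offset, 0.5, length.out = 8))[1:7]
  v <- sort(c(neg, 0, pos))
  v / max(abs(v))
}

block_starts <- function(n, block_size) seq(1L, n, by = block_size)

new_quantized_tensor <- function(codes, absmax, block_size, bits, dim,
                                 codebook = NULL, outliers = NULL,
                                 dq = NULL) {
  structure(list(codes = codes, absmax = absmax,
                 block_size = as.integer(block_size), bits = as.integer(bits),
                 dim = dim, codebook = codebook, outliers = outliers,
                 dq = dq),
            class = "quantized_tensor")
}

#' @export
print.quantized_tensor <- function(x, ...) {
  cat(sprintf(
    "<quantized_tensor> %s, %d-bit, block %d, %d blocks%s%s (%.0f bytes)\n",
    paste(x$dim, collapse = "x"), x$bits, x$block_size, length(x$absmax),
    if (!is.null(x$dq)) ", double-quantized constants" else "",
    if (!is.null(x$outliers)) sprintf(", %d outlier cols",
                                      length(x$outliers$indices)) else "",
    stored_bytes(x)))
  invisible(x)
}

# shared blockwise driver: fun(block_values, absmax) -> integer codes
quantize_blockwise <- function(W, block_size, bits, snap, outlier_threshold,
                               double_quant) {
  stopifnot(all(is.finite(W)), block_size >= 1)
  outliers <- NULL
  if (!is.null(outlier_threshold)) {
    dec <- decompose_outliers(W, outlier_threshold)
    W <- dec$inlier
    if (length(dec$outlier_indices) > 0L) {
      outliers <- list(indices = dec$outlier_indices,
                       values = dec$outlier_values)
    }
  }
  w <- as.vector(W)
  n <- length(w)
  starts <- block_starts(n, block_size)
  absmax <- numeric(length(starts))
  codes <- integer(n)
  for (bi in seq_along(starts)) {
    idx <- starts[bi]:min(starts[bi] + block_size - 1L, n)
    a <- max(abs(w[idx]))
    absmax[bi] <- a
    codes[idx] <- if (a == 0) 0L else snap(w[idx] / a)
  }
  dq <- if (double_quant) double_quantize_constants(absmax) else NULL
  new_quantized_tensor(codes, absmax, block_size, bits, dim(W),
                       codebook = if (bits == 4L) nf4_codebook() else NULL,
                       outliers = outliers, dq = dq)
}

#' Blockwise 8-bit absmax quantization
#'
#' Divides the flattened tensor into blocks of `block_size`, scales each
#' block by its absolute maximum and rounds to the signed 8-bit grid
#' `-127..127`. The worst-case round-trip error per element is
#' `absmax / 254` (half a quantization step). All-zero blocks store
#' `absmax = 0` and zero codes.
#'
#' @param W Finite numeric matrix (or vector).
#' @param block_size Elements per quantization block.
#' @param outlier_threshold If non-NULL, columns containing any entry with
#'   absolute value above this threshold are held out in higher precision
#'   (mixed-precision decomposition) before quantizing the rest.
#' @param double_quant Also quantize the per-block constants (see
#'   [double_quantize_constants()]).
#' @return A `quantized_tensor`.
#' @export
quantize_absmax8 <- function(W, block_size = 2048L, outlier_threshold = NULL,
                             double_quant = FALSE) {
  if (!is.matrix(W)) W <- as.matrix(W)
  quantize_blockwise(W, block_size, 8L,
                     snap = function(u) as.integer(round(u * 127)),
                     outlier_threshold, double_quant)
}

#' Blockwise 4-bit NormalFloat quantization
#'
#' Per block, values are normalized by the block absmax and snapped to the
#' nearest of the 16 [nf4_codebook()] levels; only the 4-bit level index is
#' stored. For normally distributed weights this codebook gives a lower
#' mean-squared error than a uniform 16-level grid.
#'
#' @inheritParams quantize_absmax8
#' @return A `quantized_tensor`.
#' @export
quantize_nf4 <- function(W, block_size = 64L, outlier_threshold = NULL,
                         double_quant = TRUE) {
  if (!is.matrix(W)) W <- as.matrix(W)
  cb <- nf4_codebook()
  mids <- (cb[-1] + cb[-length(cb)]) / 2
  quantize_blockwise(W, block_size, 4L,
                     snap = function(u) findInterval(u, mids),
                     outlier_threshold, double_quant)
}

#' Double-quantize per-block constants
#'
#' The per-block absmax constants are themselves compressed: the mean is
#' subtracted (constants are all positive, so this centers them) and the
#' shifted values are 8-bit absmax-quantized in second-level blocks. The
#' reconstruction error per constant is at most `max|shifted| / 254`.
#'
#' @param absmax Numeric vector of first-level constants.
#' @param block_size2 Constants per second-level block.
#' @return List with `mean`, `codes`, `absmax2`, `block_size2`.
#' @export
double_quantize_constants <- function(absmax, block_size2 = 256L) {
  stopifnot(length(absmax) >= 1)
  m <- mean(absmax)
  shifted <- absmax - m
  n <- length(shifted)
  starts <- block_starts(n, block_size2)
  absmax2 <- numeric(length(starts))
  codes <- integer(n)
  for (bi in seq_along(starts)) {
    idx <- starts[bi]:min(starts[bi] + block_size2 - 1L, n)
    a <- max(abs(shifted[idx]))
    absmax2[bi] <- a
    codes[idx] <- if (a == 0) 0L else as.integer(round(shifted[idx] / a * 127))
  }
  list(mean = m, codes = codes, absmax2 = absmax2,
       block_size2 = as.integer(block_size2))
}

dequantize_constants <- function(dq) {
  n <- length(dq$codes)
  starts <- block_starts(n, dq$block_size2)
  out <- numeric(n)
  for (bi in seq_along(starts)) {
    idx <- starts[bi]:min(starts[bi] + dq$block_size2 - 1L, n)
    out[idx] <- dq$codes[idx] / 127 * dq$absmax2[bi]
  }
  out + dq$mean
}

#' Mixed-precision outlier decomposition
#'
#' Splits a weight matrix into an inlier part (outlier columns zeroed) and a
#' sparse outlier part holding every column that contains an entry with
#' `|w| > threshold`. The two parts sum exactly to the original matrix.
#' Quantizing only the inlier part keeps rare large-magnitude features from
#' inflating the block scales.
#'
#' @param W Numeric matrix.
#' @param threshold Positive magnitude cutoff (conventionally 6.0).
#' @return List with `inlier` (matrix), `outlier_indices` (column indices)
#'   and `outlier_values` (matrix of the held-out columns).
#' @export
decompose_outliers <- function(W, threshold = 6) {
  stopifnot(is.matrix(W), threshold > 0)
  colmax <- apply(abs(W), 2L, max)
  idx <- which(colmax > threshold)
  vals <- W[, idx, drop = FALSE]
  inlier <- W
  if (length(idx) > 0L) inlier[, idx] <- 0
  list(inlier = inlier, outlier_indices = idx, outlier_values = vals)
}

#' Reconstruct dense weights from a quantized tensor
#'
#' Inverse map: `codes * absmax / 127` for the 8-bit grid or
#' `codebook[idx] * absmax` for NF4, with double-quantized constants
#' expanded and outlier columns re-inserted. Deterministic, and a fixed
#' point: re-quantizing a dequantized tensor reproduces it exactly.
#'
#' @param qt A `quantized_tensor`.
#' @return Numeric matrix with the original shape.
#' @export
dequantize <- function(qt) {
  stopifnot(inherits(qt, "quantized_tensor"))
  n <- length(qt$codes)
  expect_blocks <- length(block_starts(n, qt$block_size))
  if (length(qt$absmax) != expect_blocks) {
    stop("corrupted quantized tensor: expected ", expect_blocks,
         " blocks, found ", length(qt$absmax), call. = FALSE)
  }
  absmax <- if (!is.null(qt$dq)) dequantize_constants(qt$dq) else qt$absmax
  starts <- block_starts(n, qt$block_size)
  scale <- rep(absmax, times = diff(c(starts, n + 1L)))
  w <- if (qt$bits == 8L) {
    qt$codes / 127 * scale
  } else {
    qt$codebook[qt$codes + 1L] * scale
  }
  W <- matrix(w, qt$dim[1], qt$dim[2])
  if (!is.null(qt$outliers)) {
    W[, qt$outliers$indices] <- W[, qt$outliers$indices] + qt$outliers$values
  }
  W
}

#' Storage accounting for a quantized tensor
#'
#' Bytes needed to store the tensor: packed codes (1 byte per element for
#' 8-bit, half a byte for 4-bit), per-block constants (4 bytes each, or
#' their double-quantized form), and outlier columns at half precision
#' (2 bytes per value plus 4 per column index).
#'
#' @param qt A `quantized_tensor`.
#' @return Number of bytes.
#' @export
stored_bytes <- function(qt) {
  stopifnot(inherits(qt, "quantized_tensor"))
  n <- length(qt$codes)
  code_bytes <- if (qt$bits == 8L) n else ceiling(n / 2)
  const_bytes <- if (!is.null(qt$dq)) {
    length(qt$dq$codes) + 4 * length(qt$dq$absmax2) + 4
  } else {
    4 * length(qt$absmax)
  }
  out_bytes <- if (!is.null(qt$outliers)) {
    2 * length(qt$outliers$values) + 4 * length(qt$outliers$indices)
  } else {
    0
  }
  code_bytes + const_bytes + out_bytes + 4 * length(qt$dim)
}

QUANT_WEIGHT_PATTERN <- "^(layers\\.[0-9]+\\.(attn\\.(q|k|v|out)|ffn\\.fc[12])\\.weight|lm_head\\.weight)$"

#' Quantize a model's projection weights
#'
#' Applies blockwise quantization to every attention/feed-forward projection
#' and the LM head (embeddings, norms and biases stay in full precision, as
#' is conventional), then reconstructs dense weights for inference. The
#' returned model computes with the dequantized values, i.e. it behaves
#' exactly as a quantized checkpoint would after loading; the per-tensor
#' `quantized_tensor` objects are attached as attribute `"quantized"` for
#' storage accounting.
#'
#' @param model A `plm_model`.
#' @param bits 8 (absmax int8) or 4 (NF4 with double quantization).
#' @param block_size Block size; defaults to 2048 for 8-bit and 64 for
#'   4-bit.
#' @param outlier_threshold Outlier-column cutoff for the 8-bit mixed
#'   precision path; NULL disables decomposition.
#' @return A `plm_model` with attribute `"quantized"`.
#' @export
quantize_model <- function(model, bits = 4L, block_size = NULL,
                           outlier_threshold = if (bits == 8L) 6 else NULL) {
  stopifnot(inherits(model, "plm_model"), bits %in% c(4L, 8L))
  if (is.null(block_size)) block_size <- if (bits == 8L) 2048L else 64L
  qts <- list()
  W <- model$weights
  for (nm in grep(QUANT_WEIGHT_PATTERN, names(W), value = TRUE)) {
    qt <- if (bits == 8L) {
      quantize_absmax8(W[[nm]], block_size, outlier_threshold)
    } else {
      quantize_nf4(W[[nm]], block_size)
    }
    qts[[nm]] <- qt
    W[[nm]] <- dequantize(qt)
  }
  out <- new_plm_model(model$config, W, model$adapters, model$lora)
  attr(out, "quantized") <- qts
  out
}
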