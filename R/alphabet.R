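#' The 33-token ESM amino-acid alphabet
#'
#' Token alphabet used by the ESM family of protein language models: four
#' leading special tokens (`<cls>`, `<pad>`, `<eos>`, `<unk>`), the 20
#' canonical amino acids ordered by frequency, the rare/ambiguity codes
#' `X B U Z O`, the gap-like symbols `.` and `-`, a reserved null token and
#' the `<mask>` token. Token ids are 0-based so that archives written by this
#' package line up with checkpoints using the same layout.
#'
#' @return An object of class `plm_alphabet`: a list with `symbols` (ordered
#'   character vector), `cls`, `pad`, `eos`, `unk`, `mask` (0-based special
#'   ids), `aa_ids` (named integer vector mapping the 25 residue letters to
#'   ids) and `vocab_size`.
#' @examples
#' ab <- esm_alphabet()
#' ab$vocab_size            # 33
#' tokenize("MKT", ab)
#' @export
esm_alphabet <- function() {
  symbols <- c(
    "<cls>", "<pad>", "<eos>", "<unk>",
    "L", "A", "G", "V", "S", "E", "R", "T", "I", "D", "P", "K",
    "Q", "N", "F", "Y", "M", "H", "W", "C",
    "X", "B", "U", "Z", "O", ".", "-", "<null_1>", "<mask>"
  )
  aa_letters <- symbols[5:29]
  aa_ids <- stats::setNames(seq(4L, 28L), aa_letters)
  structure(
    list(
      symbols = symbols,
      cls = 0L, pad = 1L, eos = 2L, unk = 3L, mask = 32L,
      aa_ids = aa_ids,
      vocab_size = length(symbols)
    ),
    class = "plm_alphabet"
  )
}

#' @export
print.plm_alphabet <- function(x, ...) {
  cat("<plm_alphabet> ", x$vocab_size, " tokens: ",
      paste(utils::head(x$symbols, 8), collapse = " "), " ...\n", sep = "")
  invisible(x)
}

#' Residue token ids of an alphabet
#'
#' Ids that encode amino-acid residues (canonical plus rare codes), i.e.
#' everything that is neither a special token nor a gap symbol. Used to
#' decide which positions may be masked or pooled.
#'
#' @param alphabet A [esm_alphabet()] object.
#' @return Integer vector of 0-based token ids.
#' @export
residue_ids <- function(alphabet = esm_alphabet()) {
  unname(alphabet$aa_ids)
}

#' Tokenize an amino-acid sequence
#'
#' Encodes a protein sequence as `<cls>`, one id per residue, `<eos>`.
#' Lowercase letters are accepted and uppercased. Letters without a token of
#' their own (only `J` in the standard alphabet) map to `<unk>`; non-letter
#' characters are an error.
#'
#' @param sequence Single non-empty character string of residues.
#' @param alphabet A [esm_alphabet()] object.
#' @return Integer vector of 0-based token ids, length `nchar(sequence) + 2`.
#' @examples
#' tokenize("M")    # length 3: cls, M, eos
#' @export
tokenize <- function(sequence, alphabet = esm_alphabet()) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("'sequence' must be a single non-empty string", call. = FALSE)
  }
  chars <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  bad <- !grepl("^[A-Z]$", chars)
  if (any(bad)) {
    stop(sprintf("non-letter character(s) in sequence: %s",
                 paste(unique(chars[bad]), collapse = " ")), call. = FALSE)
  }
  ids <- alphabet$aa_ids[chars]
  ids[is.na(ids)] <- alphabet$unk
  c(alphabet$cls, unname(ids), alphabet$eos)
}

#' Decode token ids back to a string
#'
#' Inverse of [tokenize()] up to special tokens: special ids decode to their
#' bracketed names, residues to their one-letter codes.
#'
#' @param ids Integer vector of 0-based token ids.
#' @param alphabet A [esm_alphabet()] object.
#' @param drop_special Drop cls/eos/pad/mask tokens before joining.
#' @return Single character string.
#' @export
detokenize <- function(ids, alphabet = esm_alphabet(), drop_special = TRUE) {
  stopifnot(all(ids >= 0L), all(ids < alphabet$vocab_size))
  syms <- alphabet$symbols[ids + 1L]
  if (drop_special) {
    syms <- syms[!grepl("^<", syms)]
  }
  paste(syms, collapse = "")
}
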