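# FASTA, variant-table and weight-archive I/O. Sequence files go through
# Biostrings; tables are plain TSV with a '#'-prefixed header line stating
# units and conventions (1-based positions, scores in nats).

#' Read protein sequences from FASTA
#'
#' Order-preserving parse; the header token before the first whitespace is
#' the record id. Lowercase residues are accepted and uppercased. Duplicate
#' ids, empty sequences and non-letter characters are errors naming the
#' offending record.
#'
#' @param path FASTA file path.
#' @return data.frame with columns `id`, `sequence`.
#' @export
read_fasta <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- toupper(as.character(ss))
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  empty <- nchar(seqs) == 0L
  if (any(empty)) {
    stop("empty sequence for record(s): ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  }
  bad <- grepl("[^A-Z]", seqs)
  if (any(bad)) {
    stop("illegal (non-letter) characters in record(s): ",
         paste(ids[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(id = unname(ids), sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to FASTA
#'
#' @param records data.frame with columns `id`, `sequence`.
#' @param path Output file path.
#' @param width Residues per line.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  ss <- Biostrings::BStringSet(records$sequence)
  names(ss) <- records$id
  Biostrings::writeXStringSet(ss, path, width = as.integer(width))
  invisible(path)
}

#' Read a missense variant table
#'
#' Tab-separated columns `protein_id`, `position`, `ref`, `alt`; positions
#' are 1-based residue indices. Lines starting with `#` are comments.
#'
#' @param path TSV file path.
#' @return data.frame of variants.
#' @export
read_variants <- function(path) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("protein_id", "position", "ref", "alt")
  if (!all(need %in% names(df))) {
    stop("variant table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$position <- as.integer(df$position)
  df
}

#' Write a TSV with a commented provenance header
#'
#' @param df data.frame to write.
#' @param path Output path.
#' @param comment Character vector of header comment lines (written with a
#'   leading `#`).
#' @export
write_tsv <- function(df, path, comment = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cm in comment) writeLines(paste0("# ", cm), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Save / load model weights as a named-tensor archive
#'
#' The archive is a flat name-to-tensor map (`layers.{i}.attn.q.weight`,
#' `embed_tokens.weight`, `lm_head.weight`, ...) plus the architecture
#' config; the config is additionally written alongside as YAML so archives
#' are self-describing. Round trips are bitwise exact.
#'
#' @param model A `plm_model`.
#' @param path Archive path (an `.rds` file; `<path>.yaml` is written next
#'   to it).
#' @return `path`, invisibly (`save_weights`); a `plm_model`
#'   (`load_weights`).
#' @export
save_weights <- function(model, path) {
  stopifnot(inherits(model, "plm_model"))
  saveRDS(list(format = "plm-weights-v1",
               config = unclass(model$config),
               tensors = model$weights),
          path, version = 2)
  yaml::write_yaml(unclass(model$config), paste0(path, ".yaml"))
  invisible(path)
}

#' @rdname save_weights
#' @export
load_weights <- function(path) {
  ar <- readRDS(path)
  if (!identical(ar$format, "plm-weights-v1")) {
    stop("not a plm weight archive: ", path, call. = FALSE)
  }
  cfg <- do.call(model_config, ar$config[c("num_layers", "embed_dim",
                                           "num_heads", "ffn_dim",
                                           "vocab_size", "max_positions",
                                           "positional_mode", "activation",
                                           "norm_style", "tie_lm_head")])
  new_plm_model(cfg, ar$tensors)
}

#' Save / load LoRA adapters as a separate archive
#'
#' Adapters are serialized apart from the base weights — tensors named
#' `adapters.{layer}.{target}.{A,B}` — so trained adapters can be shared
#' and re-attached to any copy of the same base model.
#'
#' @param model An adapted `plm_model`.
#' @param path Archive path.
#' @export
save_adapters <- function(model, path) {
  if (is.null(model$adapters)) stop("model has no adapters", call. = FALSE)
  tensors <- list()
  for (nm in names(model$adapters)) {
    key <- sub("^layers\\.", "adapters.", sub("\\.attn\\.", ".", nm))
    tensors[[paste0(key, ".A")]] <- model$adapters[[nm]]$A
    tensors[[paste0(key, ".B")]] <- model$adapters[[nm]]$B
  }
  saveRDS(list(format = "plm-adapters-v1", lora = model$lora,
               tensors = tensors), path, version = 2)
  invisible(path)
}

#' @rdname save_adapters
#' @param base A non-adapted `plm_model` to attach the loaded adapters to.
#' @export
load_adapters <- function(base, path) {
  ar <- readRDS(path)
  if (!identical(ar$format, "plm-adapters-v1")) {
    stop("not a plm adapter archive: ", path, call. = FALSE)
  }
  m <- lora_attach(base, rank = ar$lora$rank, targets = ar$lora$targets,
                   scaling = ar$lora$scaling, seed = 0L)
  for (nm in names(m$adapters)) {
    key <- sub("^layers\\.", "adapters.", sub("\\.attn\\.", ".", nm))
    m$adapters[[nm]]$A <- ar$tensors[[paste0(key, ".A")]]
    m$adapters[[nm]]$B <- ar$tensors[[paste0(key, ".B")]]
  }
  m
}
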