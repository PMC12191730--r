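#' The 26-token antibody vocabulary
#'
#' Builds the fixed vocabulary used throughout the package: the 20 canonical
#' amino acids, `"X"` for unnatural or unknown residues, and the 5 special
#' tokens `<pad>`, `<mask>`, `<unk>`, `<cls>`, `<eos>`.
#'
#' @return An object of class `abmlm_vocab`: a list with `tokens` (character
#'   vector of length 26, index order is stable across runs), `index` (named
#'   integer map, 1-based), `residues` (the 21 residue tokens) and the ids of
#'   each special token (`pad_id`, `mask_id`, `unk_id`, `cls_id`, `eos_id`).
#' @examples
#' v <- build_vocab()
#' length(v$tokens)      # 26
#' v$index[["<mask>"]]
#' @export
build_vocab <- function() {
  specials <- c("<pad>", "<mask>", "<unk>", "<cls>", "<eos>")
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  tokens <- c(specials, aa, "X")
  stopifnot(length(tokens) == 26L, !anyDuplicated(tokens))
  index <- stats::setNames(seq_along(tokens), tokens)
  structure(list(
    tokens   = tokens,
    index    = index,
    residues = c(aa, "X"),
    residue_ids = unname(index[c(aa, "X")]),
    pad_id  = unname(index[["<pad>"]]),
    mask_id = unname(index[["<mask>"]]),
    unk_id  = unname(index[["<unk>"]]),
    cls_id  = unname(index[["<cls>"]]),
    eos_id  = unname(index[["<eos>"]])
  ), class = "abmlm_vocab")
}

#' @export
print.abmlm_vocab <- function(x, ...) {
  cat("abmlm vocabulary:", length(x$tokens), "tokens (",
      length(x$residues), "residue,", length(x$tokens) - length(x$residues),
      "special )\n")
  invisible(x)
}

# Map one residue string to token ids; characters outside the 21 residue
# letters become "X" (never <unk>: "X" is the unnatural-residue token).
residues_to_ids <- function(seq_string, vocab) {
  chars <- strsplit(seq_string, "", fixed = TRUE)[[1L]]
  ids <- vocab$index[chars]
  ids[is.na(ids) | ids <= 5L] <- vocab$index[["X"]]
  unname(ids)
}

#' Encode a paired heavy/light chain
#'
#' Lays out a paired sequence as `<cls>`, heavy residues, `<cls>`, `<cls>`,
#' light residues, `<eos>`, padded with `<pad>` to `max_len`. The two interior
#' `<cls>` tokens are the chain separator. The chain-qualified region mask is
#' built in the same pass.
#'
#' @param heavy,light `abmlm_chain` objects (see [annotated_chain()]).
#' @param vocab A vocabulary from [build_vocab()].
#' @param max_len Total encoded length (default 320). Pairs whose layout does
#'   not fit raise an overflow error; there is no truncation.
#' @param pair_id Optional identifier carried on the result.
#' @return An `abmlm_encoded` list: `token_ids` (integer, length `max_len`),
#'   `attention` (1 = real token, 0 = pad), `region_mask` (character, per
#'   position: `"H:FR1"` ... `"L:CDR3"`, `"SPECIAL"`, `"PAD"`), `pair_id`.
#' @export
encode_pair <- function(heavy, light, vocab, max_len = 320L, pair_id = NA_character_) {
  validate_chain(heavy)
  validate_chain(light)
  if (heavy$locus != "heavy" || light$locus == "heavy") {
    stop("encode_pair() expects a heavy chain then a light (kappa/lambda) chain",
         call. = FALSE)
  }
  nh <- nchar(heavy$sequence)
  nl <- nchar(light$sequence)
  n_real <- nh + nl + 4L  # <cls> H <cls> <cls> L <eos>
  if (n_real > max_len) {
    stop(sprintf("encoded pair length %d exceeds max_len %d (no truncation)",
                 n_real, max_len), call. = FALSE)
  }
  ids <- rep(vocab$pad_id, max_len)
  region <- rep("PAD", max_len)
  ids[1L] <- vocab$cls_id
  region[1L] <- "SPECIAL"
  h_pos <- seq_len(nh) + 1L
  ids[h_pos] <- residues_to_ids(heavy$sequence, vocab)
  region[h_pos] <- paste0("H:", region_labels_per_position(heavy))
  sep <- nh + 2L
  ids[c(sep, sep + 1L)] <- vocab$cls_id
  region[c(sep, sep + 1L)] <- "SPECIAL"
  l_pos <- seq_len(nl) + sep + 1L
  ids[l_pos] <- residues_to_ids(light$sequence, vocab)
  region[l_pos] <- paste0("L:", region_labels_per_position(light))
  ids[sep + nl + 2L] <- vocab$eos_id
  region[sep + nl + 2L] <- "SPECIAL"
  structure(list(
    token_ids = as.integer(ids),
    attention = as.integer(seq_len(max_len) <= n_real),
    region_mask = region,
    pair_id = pair_id
  ), class = "abmlm_encoded")
}

#' Decode token ids back to the two residue strings
#'
#' Inverse of [encode_pair()] on its image: splits on the double-`<cls>`
#' separator and maps residue ids back to letters.
#'
#' @param token_ids Integer vector of token ids.
#' @param vocab A vocabulary from [build_vocab()].
#' @return `list(heavy = <string>, light = <string>)`.
#' @export
decode_pair <- function(token_ids, vocab) {
  if (any(is.na(token_ids)) || any(token_ids < 1L) || any(token_ids > 26L)) {
    stop("malformed input: token ids outside the vocabulary", call. = FALSE)
  }
  real <- token_ids[token_ids != vocab$pad_id]
  n <- length(real)
  if (n < 4L || real[1L] != vocab$cls_id || real[n] != vocab$eos_id) {
    stop("malformed input: missing leading <cls> or trailing <eos>", call. = FALSE)
  }
  inner <- real[-c(1L, n)]
  sep <- which(inner[-length(inner)] == vocab$cls_id &
                 inner[-1L] == vocab$cls_id)
  if (length(sep) != 1L) {
    stop("malformed input: expected exactly one <cls><cls> chain separator",
         call. = FALSE)
  }
  h_ids <- inner[seq_len(sep - 1L)]
  l_ids <- inner[seq.int(sep + 2L, length(inner))]
  if (any(!h_ids %in% vocab$residue_ids) || any(!l_ids %in% vocab$residue_ids)) {
    stop("malformed input: non-residue token inside a chain segment", call. = FALSE)
  }
  list(heavy = paste(vocab$tokens[h_ids], collapse = ""),
       light = paste(vocab$tokens[l_ids], collapse = ""))
}

#' Encode a set of paired records into matrices
#'
#' Convenience wrapper over [encode_pair()] for model input: returns the token
#' matrix, attention matrix and region-label matrix with one row per record.
#'
#' @param records List of `abmlm_pair` records.
#' @param vocab Vocabulary.
#' @param max_len Encoded length (default 320).
#' @return List with integer matrices `tokens`, `attention`, character matrix
#'   `regions` (all n x max_len) and `pair_ids`.
#' @export
encode_dataset <- function(records, vocab, max_len = 320L) {
  n <- length(records)
  tokens <- matrix(vocab$pad_id, n, max_len)
  attention <- matrix(0L, n, max_len)
  regions <- matrix("PAD", n, max_len)
  ids <- character(n)
  for (i in seq_len(n)) {
    e <- encode_pair(records[[i]]$heavy, records[[i]]$light, vocab,
                     max_len = max_len, pair_id = records[[i]]$pair_id)
    tokens[i, ] <- e$token_ids
    attention[i, ] <- e$attention
    regions[i, ] <- e$region_mask
    ids[i] <- records[[i]]$pair_id
  }
  list(tokens = tokens, attention = attention, regions = regions,
       pair_ids = ids, max_len = as.integer(max_len))
}

#' Serialize / load the vocabulary as a JSON token list
#'
#' @param vocab Vocabulary from [build_vocab()].
#' @param path JSON file path.
#' @return `path` (write) or the reconstructed vocabulary (read), which is
#'   checked against the fixed 26-token contract.
#' @export
write_vocab <- function(vocab, path) {
  jsonlite::write_json(vocab$tokens, path)
  invisible(path)
}

#' @rdname write_vocab
#' @export
read_vocab <- function(path) {
  tokens <- unlist(jsonlite::read_json(path, simplifyVector = TRUE))
  ref <- build_vocab()
  if (!identical(tokens, ref$tokens)) {
    stop("vocabulary file does not match the fixed 26-token vocabulary",
         call. = FALSE)
  }
  ref
}
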