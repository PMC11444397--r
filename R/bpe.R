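## Byte-pair-encoding tokenizer over nucleotide alphabets.
##
## Token ids are dense 0..V-1: id 0 is the EOS delimiter, ids 1..B the base
## symbols in sorted order, and ids B+1.. the merged tokens in merge-rank
## order. Training merges the most frequent adjacent pair within sequences
## (never across sequence boundaries) until the requested vocabulary size is
## reached or no pair occurs at least twice; ties are broken
## lexicographically on the concatenated token string, so training is
## deterministic without any seed.

EOS_STRING <- "<eos>"

#' Train a BPE tokenizer on a sequence corpus
#'
#' @param x sequences (`DNAStringSet` or character vector). IUPAC ambiguity
#'   codes are treated as ordinary base symbols; they simply merge rarely.
#' @param vocabSize target vocabulary size, including the base symbols and
#'   the EOS token. Must exceed the number of distinct base symbols + 1.
#' @return a [BPETokenizer-class]. If the corpus cannot support the requested
#'   size (no adjacent pair left with frequency >= 2), a smaller vocabulary is
#'   returned with `@reachedTarget = FALSE` and a warning.
#' @export
trainBPE <- function(x, vocabSize = 64L) {
  seqs <- as.character(asDNA(x))
  if (length(seqs) == 0L) stopf("cannot train a tokenizer on an empty corpus")
  baseSymbols <- sort(unique(unlist(strsplit(seqs, "", fixed = TRUE))))
  nBase <- length(baseSymbols)
  if (vocabSize <= nBase + 1L)
    stopf("vocabSize must exceed |base symbols| + 1 = %d", nBase + 1L)
  idOf <- setNames(seq_len(nBase), baseSymbols)     # base symbol -> id (1..B)
  corpusIds <- lapply(strsplit(seqs, "", fixed = TRUE), function(ch) unname(idOf[ch]))
  targetMerges <- vocabSize - nBase - 1L
  res <- cpp_bpe_train(corpusIds, c(EOS_STRING, baseSymbols), targetMerges)
  vocab <- res$tokens
  merges <- data.frame(left = vocab[res$left + 1L], right = vocab[res$right + 1L],
                       token = vocab[res$newid + 1L], stringsAsFactors = FALSE)
  reached <- nrow(merges) == targetMerges
  if (!reached)
    warning(sprintf("corpus exhausted after %d merges; vocabulary size is %d, not %d",
                    nrow(merges), length(vocab), vocabSize), call. = FALSE)
  new("BPETokenizer", vocab = vocab, merges = merges, eosId = 0L,
      baseSymbols = baseSymbols, reachedTarget = reached)
}

mergeIds <- function(tokenizer) {
  v <- tokenizer@vocab
  list(left = match(tokenizer@merges$left, v) - 1L,
       right = match(tokenizer@merges$right, v) - 1L,
       newid = match(tokenizer@merges$token, v) - 1L)
}

#' Encode sequences into token ids
#'
#' Merges are applied greedily in merge-rank order (lowest rank first,
#' leftmost occurrences first), reproducing the training segmentation.
#'
#' @param tokenizer a [BPETokenizer-class].
#' @param x character vector of sequences over the training base symbols.
#' @param addEos append the EOS id to each encoded sequence.
#' @return a list of 0-based integer id vectors (a single vector if `x` has
#'   length 1 and `simplify` is TRUE).
#' @param simplify return a bare integer vector for a single input.
#' @export
encodeTokens <- function(tokenizer, x, addEos = FALSE, simplify = FALSE) {
  x <- as.character(x)
  chars <- strsplit(x, "", fixed = TRUE)
  idOf <- setNames(seq_along(tokenizer@baseSymbols), tokenizer@baseSymbols)
  unseen <- setdiff(unique(unlist(chars)), tokenizer@baseSymbols)
  if (length(unseen))
    stopf("symbol '%s' was not seen at tokenizer training time", unseen[1])
  ids <- lapply(chars, function(ch) unname(idOf[ch]))
  m <- mergeIds(tokenizer)
  out <- cpp_bpe_encode_many(ids, m$left, m$right, m$newid)
  if (addEos) out <- lapply(out, function(v) c(v, tokenizer@eosId))
  if (simplify && length(out) == 1L) out[[1]] else out
}

#' Decode token ids back to a nucleotide string
#'
#' @param tokenizer a [BPETokenizer-class].
#' @param ids integer vector of 0-based token ids; EOS ids are dropped.
#' @return a single character string.
#' @export
decodeTokens <- function(tokenizer, ids) {
  ids <- ids[ids != tokenizer@eosId]
  if (any(ids < 0 | ids >= length(tokenizer@vocab)))
    stopf("token id out of range")
  paste0(tokenizer@vocab[ids + 1L], collapse = "")
}

#' Mean nucleotides per token over a corpus
#'
#' Total nucleotides divided by total encoded tokens (EOS excluded). Equals 1
#' exactly for a base-only vocabulary and is non-decreasing in vocabulary
#' size.
#'
#' @param tokenizer a [BPETokenizer-class].
#' @param x sequences.
#' @return a single numeric value.
#' @export
ntPerToken <- function(tokenizer, x) {
  seqs <- as.character(asDNA(x))
  if (length(seqs) == 0L) stopf("empty corpus")
  enc <- encodeTokens(tokenizer, seqs)
  sum(nchar(seqs)) / sum(lengths(enc))
}

#' Serialize a tokenizer to JSON
#'
#' The JSON carries the merge list, the dense vocabulary and the EOS id;
#' [readTokenizerJSON()] reconstructs an identical tokenizer.
#'
#' @param tokenizer a [BPETokenizer-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeTokenizerJSON <- function(tokenizer, path) {
  obj <- list(
    merges = unname(apply(tokenizer@merges[, c("left", "right")], 1, as.list)),
    vocab = as.list(setNames(seq_along(tokenizer@vocab) - 1L, tokenizer@vocab)),
    eos_id = tokenizer@eosId,
    base_symbols = tokenizer@baseSymbols,
    reached_target = tokenizer@reachedTarget)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeTokenizerJSON
#' @export
readTokenizerJSON <- function(path) {
  obj <- jsonlite::read_json(path)
  vocab <- names(sort(unlist(obj$vocab)))
  merges <- if (length(obj$merges)) {
    data.frame(
      left = vapply(obj$merges, function(m) m[[1]], character(1)),
      right = vapply(obj$merges, function(m) m[[2]], character(1)),
      stringsAsFactors = FALSE)
  } else data.frame(left = character(0), right = character(0))
  merges$token <- if (nrow(merges)) paste0(merges$left, merges$right) else character(0)
  new("BPETokenizer", vocab = vocab, merges = merges,
      eosId = as.integer(obj$eos_id),
      baseSymbols = unlist(obj$base_symbols),
      reachedTarget = isTRUE(obj$reached_target))
}
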