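## Corpus preparation: FASTA I/O, normalisation, deduplication, token-length
## filtering and seeded splitting.

#' Read a FASTA file of nucleotide sequences
#'
#' Sequences are normalised on input (uppercase, U replaced by T, IUPAC
#' ambiguity codes retained) unless `normalize = FALSE`.
#'
#' @param path path to a FASTA file.
#' @param normalize apply [normalizeSequence()] to every record.
#' @return a named `DNAStringSet` (empty for an empty file).
#' @export
readFasta <- function(path, normalize = TRUE) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path)
  nonEmpty <- which(nzchar(trimws(lines)))
  if (length(nonEmpty) && !startsWith(trimws(lines[nonEmpty[1]]), ">"))
    stopf("malformed FASTA in %s: line %d does not start a record", path, nonEmpty[1])
  bad <- nonEmpty[!startsWith(trimws(lines[nonEmpty]), ">") &
                    grepl("[^ACGTRYSWKMBDHVNUacgtryswkmbdhvnu.-]", trimws(lines[nonEmpty]))]
  if (length(bad))
    stopf("malformed FASTA in %s: unexpected characters on line %d", path, bad[1])
  x <- Biostrings::readBStringSet(path)
  if (length(x) == 0L) return(asDNA(character(0)))
  ids <- sub("\\s.*$", "", names(x))
  seqs <- as.character(x)
  if (normalize) seqs <- normalizeSequence(seqs)
  asDNA(seqs, ids = ids)
}

#' Write sequences to FASTA
#'
#' @param x a `DNAStringSet` or named character vector.
#' @param path output path.
#' @param width line-wrap width in characters (default 60).
#' @param rna if TRUE, render T as U on output.
#' @return invisibly, the path.
#' @export
writeFasta <- function(x, path, width = 60L, rna = FALSE) {
  x <- asDNA(x)
  if (rna) {
    out <- Biostrings::RNAStringSet(chartr("T", "U", as.character(x)))
    names(out) <- names(x)
    Biostrings::writeXStringSet(out, path, width = width)
  } else {
    Biostrings::writeXStringSet(x, path, width = width)
  }
  invisible(path)
}

#' Normalise a nucleotide sequence
#'
#' Uppercases, replaces U with T and validates that every character is an
#' IUPAC nucleotide code (ambiguity codes are retained). Idempotent.
#'
#' @param raw character vector of raw sequences.
#' @return character vector of normalised sequences.
#' @export
normalizeSequence <- function(raw) {
  out <- chartr("U", "T", toupper(as.character(raw)))
  pat <- sprintf("[^%s]", paste(IUPAC_NT, collapse = ""))
  hit <- grep(pat, out)
  if (length(hit)) {
    ch <- regmatches(out[hit[1]], regexpr(pat, out[hit[1]]))
    stopf("sequence %d contains non-IUPAC character '%s'", hit[1], ch)
  }
  out
}

## Local-alignment identity between two sequences: matches / alignment
## columns of the best Smith-Waterman alignment (match +1, mismatch -1,
## gap opening 2, gap extension 1). Returns a fraction in [0, 1].
localIdentity <- function(a, b) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
    substitutionMatrix = swSubMatrix(), gapOpening = 2, gapExtension = 1)
  al <- Biostrings::nchar(pa)
  if (length(al) == 0L || al == 0L) return(0)
  Biostrings::nmatch(pa) / al
}

swSubMatrix <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1, baseOnly = FALSE)
}

## Enumerate the distinct words of length w in a sequence (ACGT only).
seqWords <- function(s, w) {
  if (nchar(s) < w) return(character(0))
  v <- substring(s, seq_len(nchar(s) - w + 1L), seq(w, nchar(s)))
  unique(v[!grepl("[^ACGT]", v)])
}

#' Greedy representative deduplication at an identity threshold
#'
#' Incremental clustering: records are scanned in input order; each record is
#' compared to the retained representatives that share at least one exact
#' 7-mer (a seed requirement that prunes hopeless comparisons), and is
#' discarded when a representative aligns to it at or above the identity
#' threshold. Identity is matches / alignment columns of the best
#' Smith-Waterman local alignment, and — as in the clustering tools this
#' stands in for — the alignment must also cover at least `minCoverage` of
#' the shorter sequence, so a short perfect local match between otherwise
#' unrelated sequences does not collapse them. Idempotent and order-stable.
#'
#' @param x a `DNAStringSet` or character vector.
#' @param identityThreshold fraction in (0, 1]; records at or above this
#'   identity to a representative are removed (default 0.8).
#' @param minCoverage minimum fraction of the shorter sequence the alignment
#'   must span for a removal (default 0.8).
#' @param seedWord word length for the shared-word prefilter (default 7).
#' @return the retained records, in input order.
#' @export
deduplicate <- function(x, identityThreshold = 0.8, minCoverage = 0.8,
                        seedWord = 7L) {
  if (identityThreshold <= 0 || identityThreshold > 1)
    stopf("identityThreshold must be in (0, 1]")
  x <- asDNA(x)
  if (length(x) == 0L) return(x)
  seqs <- as.character(x)
  keep <- logical(length(x))
  wordIndex <- new.env(hash = TRUE, parent = emptyenv())
  for (i in seq_along(seqs)) {
    words <- seqWords(seqs[i], seedWord)
    cand <- unique(unlist(lapply(words, function(w)
      if (!is.null(wordIndex[[w]])) wordIndex[[w]] else integer(0))))
    dup <- FALSE
    if (length(cand)) {
      pa <- Biostrings::pairwiseAlignment(
        Biostrings::DNAStringSet(seqs[cand]), Biostrings::DNAString(seqs[i]),
        type = "local", substitutionMatrix = swSubMatrix(),
        gapOpening = 2, gapExtension = 1)
      nAl <- Biostrings::nchar(pa)
      nm <- Biostrings::nmatch(pa)
      minLen <- pmin(nchar(seqs[cand]), nchar(seqs[i]))
      dup <- any(nAl > 0 & nAl >= minCoverage * minLen &
                   nm / pmax(nAl, 1L) >= identityThreshold)
    }
    if (!dup) {
      keep[i] <- TRUE
      for (w in words) wordIndex[[w]] <- c(wordIndex[[w]], i)
    }
  }
  x[keep]
}

#' Filter records by encoded token length
#'
#' Retains exactly the records whose BPE-encoded length (excluding EOS) is
#' strictly less than `maxTokens`.
#'
#' @param x sequences.
#' @param tokenizer a trained [BPETokenizer-class].
#' @param maxTokens token-length cutoff (records of exactly this length are
#'   removed).
#' @return the retained records.
#' @export
filterByTokenLength <- function(x, tokenizer, maxTokens) {
  x <- asDNA(x)
  if (length(x) == 0L) return(x)
  lens <- lengths(encodeTokens(tokenizer, as.character(x)))
  x[lens < maxTokens]
}

#' Split a corpus into seeded, disjoint partitions
#'
#' Applies a seeded permutation and partitions by cumulative fractions using
#' the largest-remainder method, so partition sizes differ from n * fraction
#' by less than 1 (exact on round numbers: 10000 at (0.99, 0.01) gives
#' 9900/100; 1000 at (0.6, 0.3, 0.1) gives 600/300/100).
#'
#' @param x sequences.
#' @param fractions non-negative fractions summing to 1 within 1e-9.
#' @param seed integer seed for the permutation.
#' @return a list of `DNAStringSet` partitions (named if `fractions` is
#'   named); partitions are disjoint and their union is the input.
#' @export
splitCorpus <- function(x, fractions, seed = 1L) {
  if (any(fractions < 0) || abs(sum(fractions) - 1) > 1e-9)
    stopf("fractions must be non-negative and sum to 1")
  x <- asDNA(x)
  n <- length(x)
  base <- floor(n * fractions)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * fractions - base
    add <- order(frac, decreasing = TRUE)[seq_len(rem)]
    base[add] <- base[add] + 1
  }
  perm <- withSeed(seed, sample.int(n))
  bounds <- cumsum(c(0, base))
  out <- lapply(seq_along(fractions), function(i) {
    idx <- if (base[i] == 0) integer(0) else perm[(bounds[i] + 1):bounds[i + 1]]
    x[sort(idx)]
  })
  names(out) <- names(fractions)
  out
}

#' Write a split manifest as TSV
#'
#' @param splits a named list of `DNAStringSet` partitions.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeSplitManifest <- function(splits, path) {
  nm <- if (is.null(names(splits))) as.character(seq_along(splits)) else names(splits)
  df <- do.call(rbind, lapply(seq_along(splits), function(i)
    if (length(splits[[i]])) data.frame(id = names(splits[[i]]), partition = nm[i]) else NULL))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
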