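## Local-alignment identity and the seeded novelty search with
## decoy-calibrated empirical significance.

#' Alignment identity percentage
#'
#' `100 * nIdentical / nAlign`: the proportion of matching positions among
#' the aligned columns of a local alignment.
#'
#' @param nIdentical number of identical aligned positions.
#' @param nAlign number of alignment columns (> 0).
#' @return identity as a percentage in [0, 100].
#' @export
alignmentIdentity <- function(nIdentical, nAlign) {
  if (any(nAlign <= 0)) stopf("nAlign must be positive")
  if (any(nIdentical < 0 | nIdentical > nAlign))
    stopf("need 0 <= nIdentical <= nAlign")
  100 * nIdentical / nAlign
}

## Best local alignment of one query against one target under the package
## scoring (match +1, mismatch -1, gap opening 2, gap extension 1; ambiguity
## codes score as mismatches). Returns score and Eq-style identity fields.
swAlignOne <- function(query, target) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(target), type = "local",
    substitutionMatrix = swSubMatrix(), gapOpening = 2, gapExtension = 1)
  nAl <- Biostrings::nchar(pa)
  list(score = as.numeric(Biostrings::score(pa)),
       nIdentical = as.integer(Biostrings::nmatch(pa)),
       nAlign = as.integer(nAl))
}

## Word index: word -> integer vector of target indices containing it.
buildWordIndex <- function(targets, w) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (j in seq_along(targets)) {
    for (word in seqWords(targets[j], w)) env[[word]] <- c(env[[word]], j)
  }
  env
}

bestHitSeeded <- function(query, targets, index, w) {
  words <- seqWords(query, w)
  cand <- unique(unlist(lapply(words, function(word)
    if (!is.null(index[[word]])) index[[word]] else integer(0))))
  if (length(cand) == 0L) return(NULL)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(targets[cand]), Biostrings::DNAString(query),
    type = "local", substitutionMatrix = swSubMatrix(),
    gapOpening = 2, gapExtension = 1)
  sc <- as.numeric(Biostrings::score(pa))
  j <- which.max(sc)
  list(score = sc[j],
       nIdentical = as.integer(Biostrings::nmatch(pa)[j]),
       nAlign = as.integer(Biostrings::nchar(pa)[j]),
       target = cand[j])
}

#' Seeded local-alignment novelty search
#'
#' Classifies each query by its best local alignment against a database:
#' alignment is seed-and-extend Smith-Waterman (seeds are exact shared words
#' of `minWord` nt, default 7; scoring match +1, mismatch -1, gap opening 2,
#' gap extension 1), and significance is an empirical e-value calibrated on
#' k-let-shuffled decoy queries: the e-value of a score s is the expected
#' number of decoy queries whose best database hit scores >= s, scaled to
#' the query-set size. Queries are classified as `identical_hit` (significant
#' hit at 100% identity), `partial_hit` (significant hit below 100%) or
#' `no_hit` (no seed or e-value above the threshold).
#'
#' @param queries query sequences.
#' @param database database sequences (non-empty).
#' @param minWord seed word length in nt.
#' @param evalueThreshold e-value cutoff for calling a hit (default 0.1).
#' @param nDecoys number of shuffled decoy queries used for calibration.
#' @param seed integer seed (decoy construction).
#' @return data.frame with one row per query: `query`, `target`,
#'   `score`, `n_identical`, `n_align`, `identity`, `evalue`, `class`.
#' @export
noveltySearch <- function(queries, database, minWord = 7L, evalueThreshold = 0.1,
                          nDecoys = 50L, seed = 1L) {
  queries <- asDNA(queries)
  database <- asDNA(database)
  if (length(database) == 0L) stopf("database must be non-empty")
  tseqs <- as.character(database)
  qseqs <- as.character(queries)
  index <- buildWordIndex(tseqs, minWord)
  ## decoy calibration: best scores of k-let-shuffled queries
  decoySrc <- qseqs[((seq_len(nDecoys) - 1L) %% length(qseqs)) + 1L]
  decoys <- vapply(seq_along(decoySrc), function(i)
    kletShuffleOne(decoySrc[i], 2L, seed = deriveSeed(seed, paste0("decoy", i))),
    character(1))
  decoyScores <- vapply(decoys, function(dq) {
    hit <- bestHitSeeded(dq, tseqs, index, minWord)
    if (is.null(hit)) 0 else hit$score
  }, numeric(1))
  nQ <- length(qseqs)
  evalueOf <- function(s) nQ * mean(decoyScores >= s)
  rows <- lapply(seq_len(nQ), function(i) {
    hit <- bestHitSeeded(qseqs[i], tseqs, index, minWord)
    if (is.null(hit)) {
      return(data.frame(query = names(queries)[i], target = NA_character_,
                        score = NA_real_, n_identical = NA_integer_,
                        n_align = NA_integer_, identity = NA_real_,
                        evalue = NA_real_, class = "no_hit"))
    }
    ev <- evalueOf(hit$score)
    idp <- alignmentIdentity(hit$nIdentical, hit$nAlign)
    cls <- if (ev > evalueThreshold) "no_hit"
      else if (idp == 100) "identical_hit" else "partial_hit"
    data.frame(query = names(queries)[i], target = names(database)[hit$target],
               score = hit$score, n_identical = hit$nIdentical,
               n_align = hit$nAlign, identity = idp, evalue = ev, class = cls)
  })
  do.call(rbind, rows)
}

#' Summarise a novelty search into hit percentages
#'
#' @param hits the data.frame from [noveltySearch()].
#' @return named numeric vector: `identical_pct`, `partial_pct`, `nohit_pct`.
#' @export
noveltySummary <- function(hits) {
  n <- nrow(hits)
  c(identical_pct = 100 * sum(hits$class == "identical_hit") / n,
    partial_pct = 100 * sum(hits$class == "partial_hit") / n,
    nohit_pct = 100 * sum(hits$class == "no_hit") / n)
}
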