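## k-mer distributions and Kullback-Leibler divergence.

#' Count k-mers over a set of sequences
#'
#' Sliding window of 1 nt over every sequence; all 4^k k-mers are tabulated
#' in lexicographic order. Windows containing any ambiguity code are skipped
#' (they match none of the 4^k ACGT words). Sequences shorter than k
#' contribute nothing; if no window is usable, a zero-count distribution is
#' returned with a warning.
#'
#' @param x sequences (`DNAStringSet` or character vector).
#' @param k word length (>= 1).
#' @return a [KmerDistribution-class].
#' @export
kmerCounts <- function(x, k) {
  k <- as.integer(k)
  if (k < 1L) stopf("k must be >= 1")
  x <- asDNA(x)
  words <- Biostrings::mkAllStrings(BASES, k)
  if (length(x) == 0L) {
    counts <- setNames(numeric(4^k), words)
  } else {
    cm <- Biostrings::oligonucleotideFrequency(x, width = k)
    counts <- if (is.matrix(cm)) colSums(cm) else cm
    counts <- setNames(as.numeric(counts[words]), words)
  }
  tot <- sum(counts)
  if (tot == 0)
    warning("no usable window of length k; returning a zero-count distribution",
            call. = FALSE)
  freq <- if (tot > 0) counts / tot else counts
  new("KmerDistribution", k = k, counts = counts, frequencies = freq)
}

#' Kullback-Leibler divergence between two k-mer distributions
#'
#' `sum_i P(i) * ln(P(i) / Q(i))` over all 4^k k-mers, in nats. A pseudocount
#' (default 1) is added to both count vectors before normalising, so the
#' divergence is always finite; with `pseudocount = 0`, a k-mer with P > 0
#' and Q = 0 makes the divergence infinite and the result carries
#' `attr(,"infinite") = TRUE`. Terms with P(i) = 0 contribute 0.
#'
#' @param P,Q [KmerDistribution-class] objects with the same k (P =
#'   generated, Q = reference in the generated-vs-natural comparison).
#' @param pseudocount non-negative count added to every cell of both count
#'   vectors.
#' @return the divergence in nats (non-negative).
#' @export
klDivergence <- function(P, Q, pseudocount = 1) {
  if (P@k != Q@k) stopf("P and Q must use the same k")
  if (pseudocount < 0) stopf("pseudocount must be non-negative")
  p <- P@counts + pseudocount
  q <- Q@counts + pseudocount
  if (sum(p) == 0 || sum(q) == 0) stopf("empty distribution with zero pseudocount")
  p <- p / sum(p)
  q <- q / sum(q)
  nz <- p > 0
  if (any(nz & q == 0)) {
    out <- Inf
    attr(out, "infinite") <- TRUE
    return(out)
  }
  sum(p[nz] * log(p[nz] / q[nz]))
}
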