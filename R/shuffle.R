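## Control-sequence generators: the k-let-preserving Eulerian shuffle,
## length-matched random controls, length-matched natural sampling and the
## token-level shuffle control.

## Uniform spanning arborescence of the (k-1)-mer de Bruijn multigraph,
## rooted at the walk's end vertex, via Wilson's loop-erased random walks.
## adj: list per vertex of out-neighbour vertex indices (with multiplicity).
wilsonArborescence <- function(adj, root, nV) {
  inTree <- logical(nV)
  inTree[root] <- TRUE
  nextEdge <- integer(nV)          # chosen out-edge (index into adj[[v]])
  for (start in seq_len(nV)) {
    if (inTree[start] || length(adj[[start]]) == 0L) next
    v <- start
    while (!inTree[v]) {           # random walk, remembering last exit
      e <- sample.int(length(adj[[v]]), 1L)
      nextEdge[v] <- e
      v <- adj[[v]][e]
    }
    v <- start                     # loop erasure: walk the remembered exits
    while (!inTree[v]) {
      inTree[v] <- TRUE
      v <- adj[[v]][nextEdge[v]]
    }
  }
  nextEdge
}

kletShuffleOne <- function(s, k, seed = NULL) {
  n <- nchar(s)
  if (n <= k) return(s)
  withSeed(seed, {
    if (k == 1L) {
      ch <- seqChars(s)[[1]]
      return(paste0(ch[sample.int(n)], collapse = ""))
    }
    km1 <- k - 1L
    verts <- substring(s, seq_len(n - km1 + 1L), seq(km1, n))
    vnames <- unique(verts)
    vid <- match(verts, vnames)
    nV <- length(vnames)
    nE <- n - k + 1L               # one edge per k-mer occurrence
    from <- vid[seq_len(nE)]
    to <- vid[seq_len(nE) + 1L]
    adj <- split(to, factor(from, levels = seq_len(nV)))
    adj <- lapply(adj, as.integer)
    startV <- vid[1]
    endV <- vid[length(vid)]
    ## pick each non-end vertex's last-exit edge from a uniform arborescence
    lastExit <- wilsonArborescence(adj, endV, nV)
    ## order each vertex's out-edges: non-tree edges in uniform random order,
    ## the tree edge strictly last (end vertex: all uniform)
    edgeOrder <- vector("list", nV)
    for (v in seq_len(nV)) {
      m <- length(adj[[v]])
      if (m == 0L) { edgeOrder[[v]] <- integer(0); next }
      if (v == endV) {
        edgeOrder[[v]] <- sample.int(m)
      } else {
        rest <- setdiff(seq_len(m), lastExit[v])
        edgeOrder[[v]] <- c(if (length(rest)) rest[sample.int(length(rest))], lastExit[v])
      }
    }
    ## Eulerian walk from the start vertex consuming edges in that order
    ptr <- integer(nV)
    out <- character(nE)
    v <- startV
    for (i in seq_len(nE)) {
      ptr[v] <- ptr[v] + 1L
      e <- edgeOrder[[v]][ptr[v]]
      w <- adj[[v]][e]
      out[i] <- substring(vnames[w], km1, km1)
      v <- w
    }
    paste0(vnames[startV], paste0(out, collapse = ""))
  })
}

#' k-let-preserving shuffle (random Eulerian walk)
#'
#' Shuffles each sequence while preserving its exact multiset of k-mers (and
#' hence all (k-1)-mer counts), its length and its first (k-1)-mer. The
#' shuffle is a random Eulerian walk on the (k-1)-mer de Bruijn multigraph
#' whose last-exit arborescence is drawn uniformly by Wilson's loop-erased
#' random-walk algorithm, giving a uniform draw over all valid shuffles.
#' Sequences of length <= k are returned unchanged.
#'
#' @param x sequences over {A,C,G,T}.
#' @param k k-let size to preserve (default 3, the usual choice for
#'   controlling MFE comparisons for local composition).
#' @param seed integer seed.
#' @return shuffled sequences, same container and names as the input.
#' @export
kletShuffle <- function(x, k = 3L, seed = 1L) {
  single <- is.character(x) && length(x) == 1L
  d <- asDNA(x)
  out <- vapply(seq_along(d), function(i)
    kletShuffleOne(as.character(d[[i]]), as.integer(k),
                   seed = deriveSeed(seed, paste0("klet", i))),
    character(1))
  if (single) return(out)
  asDNA(out, ids = names(d))
}

#' Length-matched uniform-random control sequences
#'
#' One uniform {A,C,G,T} sequence per input sequence, of identical length.
#'
#' @param x sequences to match.
#' @param seed integer seed.
#' @return a named `DNAStringSet` of random controls.
#' @export
randomMatched <- function(x, seed = 1L) {
  d <- asDNA(x)
  withSeed(seed, {
    lens <- Biostrings::width(d)
    seqs <- vapply(lens, function(L)
      paste0(sample(BASES, L, replace = TRUE), collapse = ""), character(1))
    asDNA(seqs, ids = paste0("random_", names(d)))
  })
}

#' Sample a pool to match a target length histogram
#'
#' Draws, without replacement, a sample from `pool` whose per-bin length
#' counts equal those of `targetLengths` (bin width default 50 nt; width 1
#' matches the exact length multiset). Errors listing the deficient bins if
#' the pool cannot cover a bin.
#'
#' @param pool candidate sequences.
#' @param targetLengths integer vector of target lengths (e.g.
#'   `width(generated)`).
#' @param binWidth histogram bin width in nt.
#' @param seed integer seed.
#' @return a `DNAStringSet` sampled from `pool`.
#' @export
lengthMatchedSample <- function(pool, targetLengths, binWidth = 50L, seed = 1L) {
  pool <- asDNA(pool)
  binOf <- function(l) (as.integer(l) - 1L) %/% as.integer(binWidth)
  tgt <- table(binOf(targetLengths))
  pb <- binOf(Biostrings::width(pool))
  avail <- table(pb)
  need <- as.integer(tgt)
  names(need) <- names(tgt)
  deficient <- names(tgt)[need > ifelse(is.na(avail[names(tgt)]), 0L, avail[names(tgt)])]
  if (length(deficient)) {
    lo <- as.integer(deficient) * binWidth + 1L
    stopf("pool cannot cover length bins starting at: %s nt",
          paste(lo, collapse = ", "))
  }
  withSeed(seed, {
    idx <- unlist(lapply(names(tgt), function(b) {
      cand <- which(pb == as.integer(b))
      cand[sample.int(length(cand), tgt[[b]])]
    }))
    pool[sort(idx)]
  })
}

#' Shuffle a token sequence before decoding
#'
#' Uniformly permutes a token id list and decodes it: nucleotides within a
#' token stay adjacent while the global token order is destroyed. Preserves
#' the token multiset and the decoded nucleotide length.
#'
#' @param ids integer vector of 0-based token ids (EOS-free).
#' @param tokenizer a [BPETokenizer-class].
#' @param seed integer seed.
#' @return the decoded nucleotide string.
#' @export
tokenShuffleDecode <- function(ids, tokenizer, seed = 1L) {
  if (any(ids == eosId(tokenizer))) stopf("ids must be EOS-free")
  perm <- withSeed(seed, sample.int(length(ids)))
  decodeTokens(tokenizer, ids[perm])
}
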