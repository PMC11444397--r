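## Synthetic corpora: Markov backgrounds, designed hairpins and
## motif-implanted binding sets. These stand in for natural sequence pools so
## the whole pipeline runs without any external download.

#' Specify a Markov background corpus
#'
#' @param order Markov order, 0 to 3. Order 0 draws bases i.i.d.
#' @param transition matrix of transition probabilities with 4 columns
#'   (A, C, G, T) and one row per order-mer context (a single row named ""
#'   for order 0). Each row must sum to 1 within 1e-9. Defaults to uniform.
#' @param lengthDistribution list with `family` ("uniform" or "fixed") and its
#'   parameters (`min`/`max`, or `length`), in nucleotides.
#' @param nSequences number of sequences to generate.
#' @param seed integer seed; all randomness flows through it.
#' @return a validated `markov_spec` list.
#' @export
markovSpec <- function(order = 0L, transition = NULL,
                       lengthDistribution = list(family = "uniform", min = 50L, max = 150L),
                       nSequences = 100L, seed = 1L) {
  order <- as.integer(order)
  if (order < 0L || order > 3L) stopf("Markov order must be between 0 and 3")
  contexts <- if (order == 0L) "" else
    apply(expand.grid(rep(list(BASES), order))[, order:1, drop = FALSE],
          1, paste0, collapse = "")
  if (is.null(transition)) {
    transition <- matrix(0.25, nrow = length(contexts), ncol = 4,
                         dimnames = list(contexts, BASES))
  }
  transition <- as.matrix(transition)
  colnames(transition) <- BASES
  if (nrow(transition) != length(contexts))
    stopf("transition matrix needs one row per %d-mer context", order)
  if (is.null(rownames(transition))) rownames(transition) <- contexts
  if (any(transition < 0) || any(abs(rowSums(transition) - 1) > 1e-9))
    stopf("each context's transition distribution must be non-negative and sum to 1")
  ld <- lengthDistribution
  minLen <- switch(ld$family,
                   uniform = as.integer(ld$min),
                   fixed = as.integer(ld$length),
                   stopf("unknown length distribution family '%s'", ld$family))
  if (minLen < 1L) stopf("minimum length must be >= 1")
  structure(list(order = order, transition = transition,
                 lengthDistribution = ld,
                 nSequences = as.integer(nSequences), seed = as.integer(seed)),
            class = "markov_spec")
}

sampleLengths <- function(ld, n) {
  switch(ld$family,
         uniform = sample.int(ld$max - ld$min + 1L, n, replace = TRUE) + ld$min - 1L,
         fixed = rep(as.integer(ld$length), n))
}

#' Generate a Markov background corpus
#'
#' Draws `nSequences` sequences over {A,C,G,T} from the specified Markov
#' chain. The first `order` positions are drawn from the context-marginal
#' stationary approximation (uniform over contexts appearing in the
#' transition table rows, then per-base), which is adequate for background
#' modelling.
#'
#' @param spec a [markovSpec()] object.
#' @return a named `DNAStringSet`.
#' @export
generateMarkovCorpus <- function(spec) {
  stopifnot(inherits(spec, "markov_spec"))
  withSeed(spec$seed, {
    n <- spec$nSequences
    if (n == 0L) return(asDNA(character(0)))
    lens <- sampleLengths(spec$lengthDistribution, n)
    maxLen <- max(lens)
    mat <- matrix(NA_character_, nrow = n, ncol = maxLen)
    if (spec$order == 0L) {
      p <- spec$transition[1, ]
      mat[] <- sample(BASES, n * maxLen, replace = TRUE, prob = p)
    } else {
      ## seed positions 1..order with order-0 marginal of the chain rows
      marg <- colMeans(spec$transition)
      for (j in seq_len(spec$order))
        mat[, j] <- sample(BASES, n, replace = TRUE, prob = marg)
      for (j in (spec$order + 1L):maxLen) {
        ctx <- apply(mat[, (j - spec$order):(j - 1L), drop = FALSE], 1, paste0, collapse = "")
        u <- runif(n)
        cum <- t(apply(spec$transition, 1, cumsum))
        idx <- match(ctx, rownames(spec$transition))
        pick <- 1L + rowSums(u > cum[idx, , drop = FALSE])
        mat[, j] <- BASES[pmin(pick, 4L)]
      }
    }
    seqs <- vapply(seq_len(n), function(i) paste0(mat[i, seq_len(lens[i])], collapse = ""),
                   character(1))
    asDNA(seqs, ids = sprintf("markov_%05d", seq_len(n)))
  })
}

#' Generate a designed-hairpin corpus
#'
#' Each record is `stem + loop + reverseComplement(stem)` with the stem and
#' loop drawn uniformly, so a perfect hairpin of at least `stemLen` base pairs
#' exists by construction. Used as a structured "generated-like" fixture for
#' folding control experiments.
#'
#' @param n number of sequences.
#' @param stemLen stem length in nt.
#' @param loopLen loop length in nt (>= 3, the minimum hairpin loop).
#' @param seed integer seed.
#' @param gcStem if TRUE the stem uses only G/C (maximally stable pairs).
#' @return a named `DNAStringSet`.
#' @export
generateHairpinCorpus <- function(n, stemLen = 10L, loopLen = 5L, seed = 1L,
                                  gcStem = FALSE) {
  if (loopLen < 3L) stopf("loopLen must be >= 3 (minimum hairpin loop)")
  withSeed(seed, {
    if (n == 0L) return(asDNA(character(0)))
    alphaStem <- if (gcStem) c("G", "C") else BASES
    seqs <- vapply(seq_len(n), function(i) {
      stem <- paste0(sample(alphaStem, stemLen, replace = TRUE), collapse = "")
      loop <- paste0(sample(BASES, loopLen, replace = TRUE), collapse = "")
      rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(stem)))
      paste0(stem, loop, rc)
    }, character(1))
    asDNA(seqs, ids = sprintf("hairpin_%05d", seq_len(n)))
  })
}

#' Specify a sequence motif for implantation
#'
#' @param pwm 4 x w probability matrix (rows A, C, G, T); each column must sum
#'   to 1 within 1e-9. Width w must be between 4 and 20.
#' @param implantRate fraction of positive sequences carrying a sampled motif
#'   instance.
#' @param seed integer seed.
#' @return a validated `motif_spec` list.
#' @export
motifSpec <- function(pwm, implantRate = 1.0, seed = 1L) {
  pwm <- as.matrix(pwm)
  if (nrow(pwm) != 4L) stopf("pwm must have 4 rows (A, C, G, T)")
  rownames(pwm) <- BASES
  w <- ncol(pwm)
  if (w < 4L || w > 20L) stopf("motif width must be between 4 and 20 nt")
  if (any(pwm < 0) || any(abs(colSums(pwm) - 1) > 1e-9))
    stopf("each PWM column must be a probability distribution")
  if (implantRate < 0 || implantRate > 1) stopf("implantRate must be in [0, 1]")
  structure(list(pwm = pwm, width = w, implantRate = implantRate,
                 seed = as.integer(seed)), class = "motif_spec")
}

#' Build a PWM from a consensus string
#'
#' @param consensus string over {A,C,G,T}.
#' @param concentration probability mass on the consensus base per position
#'   (remainder spread over the other three bases).
#' @return a 4 x w probability matrix usable in [motifSpec()].
#' @export
consensusPWM <- function(consensus, concentration = 1.0) {
  ch <- seqChars(consensus)[[1]]
  off <- (1 - concentration) / 3
  pwm <- matrix(off, nrow = 4, ncol = length(ch), dimnames = list(BASES, NULL))
  for (j in seq_along(ch)) pwm[ch[j], j] <- concentration
  pwm
}

#' Generate motif-implanted positive and background negative sets
#'
#' Emulates a CLIP-style binding dataset: positives are background sequences
#' in which, at rate `implantRate`, a motif instance sampled from the PWM
#' overwrites w positions at a uniformly random offset (overwriting rather
#' than inserting preserves sequence length, keeping length-matched
#' comparisons valid); negatives are pure background.
#'
#' @param background a [markovSpec()] for the background model.
#' @param motif a [motifSpec()].
#' @param nPos,nNeg numbers of positive and negative sequences.
#' @return a named `DNAStringSet` of length `nPos + nNeg` with a `label`
#'   column ("positive"/"negative") in `mcols()`.
#' @export
generateBindingSets <- function(background, motif, nPos, nNeg) {
  stopifnot(inherits(background, "markov_spec"), inherits(motif, "motif_spec"))
  minLen <- switch(background$lengthDistribution$family,
                   uniform = background$lengthDistribution$min,
                   fixed = background$lengthDistribution$length)
  if (motif$width > minLen)
    stopf("motif width (%d) exceeds the minimum sequence length (%d)",
          motif$width, minLen)
  bgPos <- background; bgPos$nSequences <- as.integer(nPos)
  bgPos$seed <- deriveSeed(background$seed, "binding_pos")
  bgNeg <- background; bgNeg$nSequences <- as.integer(nNeg)
  bgNeg$seed <- deriveSeed(background$seed, "binding_neg")
  pos <- generateMarkovCorpus(bgPos)
  neg <- generateMarkovCorpus(bgNeg)
  pos <- withSeed(deriveSeed(motif$seed, "implant"), {
    chars <- seqChars(pos)
    w <- motif$width
    for (i in seq_along(chars)) {
      if (runif(1) <= motif$implantRate && motif$implantRate > 0) {
        inst <- vapply(seq_len(w), function(j)
          sample(BASES, 1, prob = motif$pwm[, j]), character(1))
        start <- sample.int(length(chars[[i]]) - w + 1L, 1)
        chars[[i]][start:(start + w - 1L)] <- inst
      }
    }
    asDNA(vapply(chars, paste0, character(1), collapse = ""))
  })
  out <- asDNA(c(as.character(pos), as.character(neg)),
               ids = c(sprintf("pos_%05d", seq_len(nPos)),
                       sprintf("neg_%05d", seq_len(nNeg))))
  mcols(out)$label <- rep(c("positive", "negative"), c(nPos, nNeg))
  out
}

#' Write sequence labels as a two-column TSV
#'
#' @param x a `DNAStringSet` with a `label` column in `mcols()`.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeLabelTSV <- function(x, path) {
  df <- data.frame(id = names(x), label = mcols(x)$label)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
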