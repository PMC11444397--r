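## Decoding: greedy, beam and top-k sampling with temperature, plus the
## deterministic prefix-enumeration protocol. Everything runs through
## nextTokenLogProbs(), so any model implementing that generic can be decoded.

#' Specify a decoding strategy
#'
#' @param strategy one of "greedy", "beam", "topk".
#' @param beamWidth beam width (>= 1; width 1 is exactly greedy).
#' @param topK number of highest-probability tokens to renormalise and sample
#'   from (1 is exactly greedy; V is unrestricted sampling).
#' @param temperature positive real dividing the logits before softmax
#'   (default 1.0).
#' @param maxNewTokens generation cap in tokens (default: the model decides,
#'   typically the context length).
#' @param seed seed for stochastic sampling.
#' @return a `sampling_spec` list.
#' @export
samplingSpec <- function(strategy = c("topk", "greedy", "beam"),
                         beamWidth = 5L, topK = 40L, temperature = 1.0,
                         maxNewTokens = NULL, seed = 1L) {
  strategy <- match.arg(strategy)
  if (beamWidth < 1L) stopf("beamWidth must be >= 1")
  if (topK < 1L) stopf("topK must be >= 1")
  if (temperature <= 0) stopf("temperature must be positive")
  structure(list(strategy = strategy, beamWidth = as.integer(beamWidth),
                 topK = as.integer(topK), temperature = temperature,
                 maxNewTokens = maxNewTokens, seed = as.integer(seed)),
            class = "sampling_spec")
}

## Temperature-scaled next-token log distribution for a context.
scaledNextLogProbs <- function(model, ids, temperature) {
  lp <- nextTokenLogProbs(model, ids)
  if (temperature != 1) {
    lp <- lp / temperature
    lp <- lp - max(lp)
    lp <- lp - log(sum(exp(lp)))
  }
  lp
}

contextCap <- function(model) {
  if (is(model, "LanguageModel")) model@config@contextLen else 64L
}

#' Generate one sequence from a nucleotide prefix
#'
#' Decodes autoregressively from `[EOS] + encode(prefix)`: the prefix is
#' encoded to BPE tokens and decoding continues at token granularity until
#' EOS is emitted or the generation cap is reached (capped sequences carry a
#' `truncated` attribute). Temperature divides the logits before softmax;
#' top-k renormalises over the k most probable tokens; beam search returns
#' the completed hypothesis with the highest summed log-probability, breaking
#' ties towards the lexicographically smaller token id sequence.
#'
#' @param model a [LanguageModel-class] or [TableModel-class].
#' @param tokenizer a [BPETokenizer-class].
#' @param prefix nucleotide prefix string (may be "").
#' @param spec a [samplingSpec()].
#' @return the generated nucleotide string (prefix included, EOS stripped).
#' @export
generateSequence <- function(model, tokenizer, prefix = "", spec = samplingSpec()) {
  eos <- eosId(tokenizer)
  pre <- if (nzchar(prefix)) encodeTokens(tokenizer, prefix, simplify = TRUE) else integer(0)
  ids <- c(eos, pre)
  cap <- spec$maxNewTokens
  if (is.null(cap)) cap <- contextCap(model) - length(ids)
  if (length(ids) >= contextCap(model)) stopf("prefix does not fit in the context window")
  out <- switch(spec$strategy,
    greedy = decodeGreedy(model, ids, eos, cap, contextCap(model)),
    beam = decodeBeam(model, ids, eos, cap, spec$beamWidth, contextCap(model)),
    topk = withSeed(spec$seed,
      decodeTopK(model, ids, eos, cap, spec$topK, spec$temperature, contextCap(model))))
  res <- decodeTokens(tokenizer, out$ids[-1])      # drop leading EOS
  attr(res, "truncated") <- out$truncated
  res
}

decodeGreedy <- function(model, ids, eos, cap, ctx) {
  newCount <- 0L
  while (newCount < cap && length(ids) < ctx) {
    lp <- nextTokenLogProbs(model, ids)
    nxt <- which.max(lp) - 1L
    if (nxt == eos) return(list(ids = ids, truncated = FALSE))
    ids <- c(ids, nxt)
    newCount <- newCount + 1L
  }
  list(ids = ids, truncated = TRUE)
}

decodeTopK <- function(model, ids, eos, cap, k, temperature, ctx) {
  newCount <- 0L
  while (newCount < cap && length(ids) < ctx) {
    lp <- scaledNextLogProbs(model, ids, temperature)
    k2 <- min(k, length(lp))
    topIdx <- order(lp, decreasing = TRUE)[seq_len(k2)]
    p <- exp(lp[topIdx] - max(lp[topIdx]))
    nxt <- topIdx[sample.int(k2, 1, prob = p)] - 1L
    if (nxt == eos) return(list(ids = ids, truncated = FALSE))
    ids <- c(ids, nxt)
    newCount <- newCount + 1L
  }
  list(ids = ids, truncated = TRUE)
}

## Beam search with raw summed log-probability scoring (no length
## normalisation). Each live hypothesis is expanded over the full vocabulary;
## the top `width` candidates survive, and a surviving candidate that emits
## EOS is frozen (reducing the live width) and competes with the remaining
## hypotheses at the end. With width 1 this reduces exactly to greedy
## decoding. Ties break towards the smaller token id sequence.
decodeBeam <- function(model, ids, eos, cap, width, ctx) {
  live <- list(list(ids = ids, lp = 0, done = FALSE))
  frozen <- list()
  newCount <- 0L
  while (length(live) > 0 && newCount < cap && (length(ids) + newCount) < ctx) {
    cands <- list()
    for (h in live) {
      lp <- nextTokenLogProbs(model, h$ids)
      for (tok in seq_along(lp)) {
        cands[[length(cands) + 1L]] <-
          list(ids = c(h$ids, tok - 1L), lp = h$lp + lp[tok],
               done = (tok - 1L) == eos)
      }
    }
    cands <- beamRank(cands)
    cands <- cands[seq_len(min(width, length(cands)))]
    live <- list()
    for (cand in cands) {
      if (cand$done) {
        cand$ids <- head(cand$ids, -1L)           # drop the EOS
        frozen[[length(frozen) + 1L]] <- cand
      } else {
        live[[length(live) + 1L]] <- cand
      }
    }
    newCount <- newCount + 1L
  }
  for (h in live) { h$truncatedFlag <- TRUE; frozen[[length(frozen) + 1L]] <- h }
  best <- beamRank(frozen)[[1]]
  list(ids = best$ids, truncated = isTRUE(best$truncatedFlag))
}

## Order hypotheses by score desc, ties by lexicographically smaller id
## sequence.
beamRank <- function(hyps) {
  if (length(hyps) <= 1L) return(hyps)
  keys <- vapply(hyps, function(h)
    paste(sprintf("%06d", h$ids), collapse = ","), character(1))
  scores <- vapply(hyps, function(h) h$lp, numeric(1))
  hyps[order(-scores, keys)]
}

#' Enumerate all nucleotide prefixes of a given length
#'
#' All |alphabet|^length strings in lexicographic order; length 5 over
#' {A, U, G, C} yields the 1,024 prefixes used to drive deterministic
#' decoding.
#'
#' @param alphabet character vector of symbols (default c("A","U","G","C");
#'   alphabet order defines the enumeration order).
#' @param length prefix length (>= 0; length 0 yields "").
#' @return character vector of prefixes.
#' @export
enumeratePrefixes <- function(alphabet = c("A", "U", "G", "C"), length = 5L) {
  alphabet <- sort(as.character(alphabet))
  if (length == 0L) return("")
  grid <- expand.grid(rep(list(alphabet), length), stringsAsFactors = FALSE)
  ## column 1 varies fastest in expand.grid; reorder for lexicographic output
  out <- do.call(paste0, grid[, rev(seq_len(length)), drop = FALSE])
  sort(out)
}

#' Generate a batch of sequences
#'
#' For stochastic (top-k) decoding: `n` independent seeded draws from the
#' empty prefix. For the deterministic strategies (greedy, beam) the batch is
#' driven by prefix enumeration: all `4^prefixLen` nucleotide prefixes are
#' decoded once each (U in prefixes is normalised to the internal T).
#'
#' @param model a model.
#' @param tokenizer a [BPETokenizer-class].
#' @param spec a [samplingSpec()].
#' @param n batch size for top-k sampling (ignored for greedy/beam).
#' @param prefixLen prefix length for greedy/beam enumeration (default 5).
#' @return a named `DNAStringSet` of generated sequences.
#' @export
generateBatch <- function(model, tokenizer, spec = samplingSpec(), n = 100L,
                          prefixLen = 5L) {
  if (spec$strategy == "topk") {
    seqs <- vapply(seq_len(n), function(i) {
      s2 <- spec; s2$seed <- deriveSeed(spec$seed, paste0("draw", i))
      as.character(generateSequence(model, tokenizer, "", s2))
    }, character(1))
    asDNA(seqs, ids = sprintf("%s_%05d", spec$strategy, seq_len(n)))
  } else {
    prefixes <- enumeratePrefixes(length = prefixLen)
    seqs <- vapply(prefixes, function(p) {
      as.character(generateSequence(model, tokenizer, chartr("U", "T", p), spec))
    }, character(1))
    asDNA(unname(seqs), ids = sprintf("%s_%s", spec$strategy, prefixes))
  }
}
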