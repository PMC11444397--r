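## Session-cached fixtures shared by the heavier tests: a desk tokenizer and
## a briefly pre-trained background model. Built once per test run.

.fixtureCache <- new.env(parent = emptyenv())

fixtureBackgroundCorpus <- function() {
  if (is.null(.fixtureCache$bg)) {
    spec <- markovSpec(nSequences = 250L,
                       lengthDistribution = list(family = "uniform",
                                                 min = 40L, max = 80L),
                       seed = 101L)
    .fixtureCache$bg <- generateMarkovCorpus(spec)
  }
  .fixtureCache$bg
}

fixtureTokenizer <- function() {
  if (is.null(.fixtureCache$tok))
    .fixtureCache$tok <- trainBPE(fixtureBackgroundCorpus(), vocabSize = 64L)
  .fixtureCache$tok
}

fixturePretrainedModel <- function() {
  if (is.null(.fixtureCache$model)) {
    tok <- fixtureTokenizer()
    cfg <- modelConfig(vocabSize = vocabSize(tok), seed = 202L)
    stream <- makeTrainingStream(fixtureBackgroundCorpus(), tok,
                                 cfg@contextLen, seed = 1L)
    fit <- trainModel(buildModel(cfg), stream,
                      trainConfig(epochs = 3L, batchSize = 16L, seed = 2L))
    .fixtureCache$model <- fit$model
  }
  .fixtureCache$model
}

## Motif-implanted binding sets used by scorer/binder tests.
fixtureBindingSets <- function(nPos = 200L, nNeg = 200L, seed = 42L) {
  bg <- markovSpec(nSequences = 1L,
                   lengthDistribution = list(family = "uniform",
                                             min = 40L, max = 60L),
                   seed = seed)
  mot <- motifSpec(consensusPWM("TGCATGCA", 0.95), implantRate = 1, seed = 7L)
  sets <- generateBindingSets(bg, mot, nPos = nPos, nNeg = nNeg)
  list(positives = sets[S4Vectors::mcols(sets)$label == "positive"],
       negatives = sets[S4Vectors::mcols(sets)$label == "negative"])
}

## Deliberately memorizable positive set: a handful of distinct motif-bearing
## sequences repeated many times (redundancy is the point: the validation
## split then genuinely improves while the model memorizes).
fixtureMemorizableSet <- function(nDistinct = 5L, nCopies = 10L, len = 24L,
                                  seed = 123L) {
  distinct <- rnalm:::withSeed(seed, {
    vapply(seq_len(nDistinct), function(i) {
      s <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      s[9:16] <- strsplit("TGCATGCA", "")[[1]]
      paste0(s, collapse = "")
    }, character(1))
  })
  seqs <- rep(distinct, each = nCopies)
  list(distinct = distinct,
       set = Biostrings::DNAStringSet(
         setNames(seqs, sprintf("mem_%03d", seq_along(seqs)))))
}

toyTableModel <- function() {
  tableModel(4L, table = list(
    "0" = c(0.0, 0.6, 0.4, 0.0),
    "1" = c(0.1, 0.1, 0.1, 0.7),
    "2" = c(0.1, 0.2, 0.2, 0.5),
    "3" = c(0.9, 0.05, 0.03, 0.02)), order = 1L)
}

baseOnlyTokenizer <- function() {
  ## a tokenizer whose vocabulary is EOS + the four bases (zero merges)
  suppressWarnings(trainBPE(c("ACGT", "TGCA"), vocabSize = 6L))
}
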