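test_that("BPE merges follow pair frequency with deterministic tie-breaking", {
  tok <- suppressWarnings(trainBPE(rep("AAAA", 100), vocabSize = 7L))
  ## only A present: first merge AA; second merges involving AA
  expect_identical(tok@merges$token[1], "AA")
  expect_true(tok@merges$token[2] %in% c("AAA", "AAAA"))
  expect_identical(length(encodeTokens(tok, "AAAA", simplify = TRUE)), 1L)
  ## deterministic retraining
  tok2 <- suppressWarnings(trainBPE(rep("AAAA", 100), vocabSize = 7L))
  expect_identical(tok@merges, tok2@merges)
  expect_identical(tok@vocab, tok2@vocab)
})

test_that("minimal vocabulary gives per-nucleotide encoding", {
  tok <- baseOnlyTokenizer()
  expect_identical(nrow(tok@merges), 0L)
  s <- randomSeq(30)
  expect_identical(length(encodeTokens(tok, s, simplify = TRUE)), 30L)
  expect_identical(ntPerToken(tok, s), 1.0)
})

test_that("encode/decode round-trips and merges apply leftmost-first", {
  corpus <- rnalm:::withSeed(7, vapply(1:50, function(i) randomSeq(60), character(1)))
  tok <- trainBPE(corpus, vocabSize = 32L)
  for (s in corpus[1:10])
    expect_identical(decodeTokens(tok, encodeTokens(tok, s, simplify = TRUE)), s)
  ## leftmost-first greedy application: with only an AA merge available,
  ## AAA encodes as [AA, A]
  tokA <- suppressWarnings(trainBPE(rep("AA", 100), vocabSize = 7L))
  ids <- encodeTokens(tokA, "AAA", simplify = TRUE)
  expect_identical(tokA@vocab[ids + 1L], c("AA", "A"))
  expect_error(encodeTokens(tok, "ACGN"), "'N'")
})

test_that("EOS appears only when requested and never mid-sequence", {
  tok <- fixtureTokenizer()
  enc <- encodeTokens(tok, c("ACGTACGT", "TTTT"), addEos = TRUE)
  for (ids in enc) {
    expect_identical(sum(ids == eosId(tok)), 1L)
    expect_identical(ids[length(ids)], eosId(tok))
  }
  enc2 <- encodeTokens(tok, "ACGTACGT")
  expect_false(any(enc2[[1]] == eosId(tok)))
})

test_that("replaying merges regenerates the vocabulary", {
  tok <- fixtureTokenizer()
  rebuilt <- c("<eos>", tok@baseSymbols)
  for (i in seq_len(nrow(tok@merges)))
    rebuilt <- c(rebuilt, paste0(tok@merges$left[i], tok@merges$right[i]))
  expect_identical(rebuilt, tok@vocab)
})

test_that("nt-per-token grows with vocabulary size and matches hand counts", {
  corpus <- rnalm:::withSeed(11, vapply(1:100, function(i) randomSeq(80), character(1)))
  tokSmall <- suppressWarnings(trainBPE(corpus, vocabSize = 8L))
  tokLarge <- trainBPE(corpus, vocabSize = 64L)
  expect_gte(ntPerToken(tokLarge, corpus), ntPerToken(tokSmall, corpus))
  ## degenerate corpus: AAAA becomes one 4-nt token
  tokA <- suppressWarnings(trainBPE(rep("AAAA", 100), vocabSize = 8L))
  expect_identical(ntPerToken(tokA, rep("AAAA", 100)), 4.0)
  expect_error(ntPerToken(tokA, character(0)), "empty")
})

test_that("tokenizer JSON serialisation round-trips", {
  tok <- fixtureTokenizer()
  tmp <- tempfile(fileext = ".json")
  writeTokenizerJSON(tok, tmp)
  back <- readTokenizerJSON(tmp)
  expect_identical(back@vocab, tok@vocab)
  expect_identical(back@merges$token, tok@merges$token)
  expect_identical(back@eosId, tok@eosId)
  s <- randomSeq(40)
  expect_identical(encodeTokens(back, s), encodeTokens(tok, s))
})

test_that("a corpus too small for the requested vocabulary warns and flags", {
  expect_warning(tok <- trainBPE(c("ACGT", "TGCA"), vocabSize = 20L), "exhausted")
  expect_false(tok@reachedTarget)
  expect_lt(vocabSize(tok), 20L)
})
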