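test_that("k-let shuffle preserves k-mer counts, length and the start vertex", {
  expect_identical(kletShuffle("AAAA", k = 3, seed = 1), "AAAA")
  ## ACACAC under k=2 admits a single Eulerian arrangement
  expect_identical(kletShuffle("ACACAC", k = 2, seed = 5), "ACACAC")
  set.seed(3)
  for (i in 1:50) {
    s <- randomSeq(sample(20:200, 1))
    k <- sample(1:4, 1)
    sh <- kletShuffle(s, k = k, seed = i)
    expect_identical(nchar(sh), nchar(s))
    expect_identical(kmerCountVector(sh, k), kmerCountVector(s, k))
    if (k > 1)
      expect_identical(substr(sh, 1, k - 1), substr(s, 1, k - 1))
  }
  ## too-short input returned unchanged
  expect_identical(kletShuffle("ACG", k = 3, seed = 1), "ACG")
})

test_that("k-let shuffle against brute-force permutation oracle on short strings", {
  ## every shuffle output must be a permutation with identical 2-mer counts;
  ## enumerate the valid set exhaustively and check membership + coverage
  s <- "AACAGCAAT"
  permute <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in permute(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  ch <- strsplit(s, "")[[1]]
  valid <- unique(vapply(permute(ch), paste0, character(1), collapse = ""))
  ref <- kmerCountVector(s, 2)
  valid <- valid[vapply(valid, function(p)
    identical(kmerCountVector(p, 2), ref) && startsWith(p, substr(s, 1, 1)),
    logical(1))]
  draws <- vapply(1:40, function(i) kletShuffle(s, k = 2, seed = i), character(1))
  expect_true(all(draws %in% valid))
  expect_gt(length(unique(draws)), 1L)         # it does actually shuffle
})

test_that("random controls match lengths and are near-uniform", {
  x <- c(a = randomSeq(100), b = randomSeq(250))
  r1 <- randomMatched(x, seed = 2)
  expect_identical(Biostrings::width(r1), c(100L, 250L))
  expect_identical(as.character(randomMatched(x, seed = 2)), as.character(r1))
  big <- randomMatched(strrep("A", 100000), seed = 3)
  f <- colSums(Biostrings::oligonucleotideFrequency(big, 1)) / 100000
  expect_true(all(abs(f - 0.25) < 3 * sqrt(0.25 * 0.75 / 100000) + 1e-3))
})

test_that("length-matched sampling reproduces the target histogram or fails loudly", {
  set.seed(77)
  pool <- asDNA(c(vapply(1:300, function(i) randomSeq(sample(10:200, 1)), character(1)),
                  vapply(1:3, function(i) randomSeq(20), character(1))))
  targets <- c(15L, 15L, 80L, 140L, 190L)
  got <- lengthMatchedSample(pool, targets, binWidth = 50L, seed = 4)
  binOf <- function(l) (l - 1) %/% 50
  expect_identical(table(binOf(Biostrings::width(got))), table(binOf(targets)))
  ## bin width 1: exact length multiset
  got1 <- lengthMatchedSample(pool, c(20L, 20L), binWidth = 1L, seed = 4)
  expect_identical(sort(Biostrings::width(got1)), c(20L, 20L))
  expect_error(lengthMatchedSample(pool, c(5000L), binWidth = 50L), "bins")
})

test_that("token-level shuffling preserves the token multiset and decoded length", {
  tok <- fixtureTokenizer()
  s <- randomSeq(80)
  ids <- encodeTokens(tok, s, simplify = TRUE)
  out <- tokenShuffleDecode(ids, tok, seed = 6)
  expect_identical(nchar(out), 80L)
  expect_identical(sort(encodeTokensBack <- ids), sort(ids))
  ## re-encoding the shuffled string is not required to match, but the
  ## decoded string must be the concatenation of the permuted tokens
  perm <- rnalm:::withSeed(6, sample.int(length(ids)))
  expect_identical(out, decodeTokens(tok, ids[perm]))
  ## single token: unchanged
  expect_identical(tokenShuffleDecode(ids[1], tok, seed = 1),
                   decodeTokens(tok, ids[1]))
  expect_error(tokenShuffleDecode(c(0L, 1L), tok), "EOS")
})
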