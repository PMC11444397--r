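test_that("order-0 Markov generation honours degenerate and uniform distributions", {
  ## all probability mass on A
  spec <- markovSpec(order = 0L,
                     transition = matrix(c(1, 0, 0, 0), 1, 4),
                     lengthDistribution = list(family = "fixed", length = 5L),
                     nSequences = 3L, seed = 1L)
  out <- generateMarkovCorpus(spec)
  expect_equal(as.character(out), rep("AAAAA", 3), ignore_attr = TRUE)

  ## uniform: per-base frequencies within a 3-sigma binomial band
  spec <- markovSpec(order = 0L,
                     lengthDistribution = list(family = "fixed", length = 100L),
                     nSequences = 10000L, seed = 2L)
  out <- generateMarkovCorpus(spec)
  freqs <- colSums(Biostrings::oligonucleotideFrequency(out, 1))
  freqs <- freqs / sum(freqs)
  expect_true(all(freqs > 0.24 & freqs < 0.26))
})

test_that("Markov corpora are seed-deterministic and ACGT-only", {
  spec <- markovSpec(order = 1L, nSequences = 50L, seed = 9L)
  a <- generateMarkovCorpus(spec)
  b <- generateMarkovCorpus(spec)
  expect_identical(as.character(a), as.character(b))
  expect_false(any(grepl("[^ACGT]", as.character(a))))
  expect_length(a, 50L)
})

test_that("invalid Markov specs are rejected", {
  expect_error(markovSpec(transition = matrix(c(0.5, 0.2, 0.2, 0.2), 1, 4)),
               "sum to 1")
  expect_error(markovSpec(order = 5L), "order")
  expect_error(markovSpec(lengthDistribution = list(family = "fixed", length = 0L)),
               "length")
})

test_that("order-0 k-mer frequencies factorise into base frequencies", {
  spec <- markovSpec(order = 0L,
                     transition = matrix(c(0.4, 0.3, 0.2, 0.1), 1, 4),
                     lengthDistribution = list(family = "fixed", length = 100L),
                     nSequences = 10000L, seed = 5L)
  out <- generateMarkovCorpus(spec)
  ## non-overlapping 2-mers are independent draws, so the chi-square
  ## approximation applies (overlapping windows would inflate the statistic)
  seqs <- as.character(out)
  pairs <- unlist(lapply(seqs, function(s)
    substring(s, seq(1, nchar(s) - 1, by = 2), seq(2, nchar(s), by = 2))))
  obs <- table(factor(pairs, levels = names(kmerCounts("AA", 2)@counts)))
  p <- c(0.4, 0.3, 0.2, 0.1)
  ## lexicographic 2-mers: first base varies slowest
  exp2 <- as.vector(t(outer(p, p))) * length(pairs)
  chi <- sum((as.numeric(obs) - exp2)^2 / exp2)
  expect_lt(chi, qchisq(0.999, df = 15))
})

test_that("hairpin corpus is stem + loop + reverse-complement(stem)", {
  hp <- generateHairpinCorpus(5L, stemLen = 3L, loopLen = 3L, seed = 4L)
  for (s in as.character(hp)) {
    expect_identical(nchar(s), 9L)
    stem <- substr(s, 1, 3)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(stem)))
    expect_identical(substr(s, 7, 9), rc)
  }
  expect_length(generateHairpinCorpus(0L, seed = 1L), 0L)
  expect_error(generateHairpinCorpus(3L, loopLen = 2L), "loopLen")
})

test_that("hairpin sequences fold with at least stemLen base pairs", {
  hp <- generateHairpinCorpus(10L, stemLen = 4L, loopLen = 3L, seed = 8L)
  for (s in as.character(hp)) {
    f <- foldScore(s)
    expect_gte(sum(strsplit(f@structure, "")[[1]] == "("), 4L)
  }
})

test_that("motif implantation respects rate, position and labels", {
  bg <- markovSpec(nSequences = 1L,
                   lengthDistribution = list(family = "fixed", length = 40L),
                   seed = 11L)
  mot <- motifSpec(consensusPWM("TTTTGGGG"), implantRate = 1, seed = 3L)
  sets <- generateBindingSets(bg, mot, nPos = 100L, nNeg = 100L)
  expect_length(sets, 200L)
  expect_identical(sum(S4Vectors::mcols(sets)$label == "positive"), 100L)
  pos <- as.character(sets[S4Vectors::mcols(sets)$label == "positive"])
  expect_true(all(grepl("TTTTGGGG", pos)))
  expect_true(all(nchar(pos) == 40L))       # implant overwrites, not inserts

  ## implant rate 0: positives indistinguishable from negatives in match count
  mot0 <- motifSpec(consensusPWM("TTTTGGGG"), implantRate = 0, seed = 3L)
  sets0 <- generateBindingSets(bg, mot0, nPos = 200L, nNeg = 200L)
  p0 <- as.character(sets0[S4Vectors::mcols(sets0)$label == "positive"])
  n0 <- as.character(sets0[S4Vectors::mcols(sets0)$label == "negative"])
  expect_lte(abs(sum(grepl("TTTTGGGG", p0)) - sum(grepl("TTTTGGGG", n0))), 2L)
})

test_that("motif wider than the minimum sequence length is rejected", {
  bg <- markovSpec(nSequences = 1L,
                   lengthDistribution = list(family = "fixed", length = 6L),
                   seed = 1L)
  mot <- motifSpec(consensusPWM("ACGTACGT"), seed = 1L)
  expect_error(generateBindingSets(bg, mot, 5L, 5L), "width")
})

test_that("PWM columns must be distributions and width bounded", {
  bad <- consensusPWM("ACGTAC"); bad[1, 1] <- 0.5
  expect_error(motifSpec(bad), "distribution")
  expect_error(motifSpec(consensusPWM("ACG")), "width")
})
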