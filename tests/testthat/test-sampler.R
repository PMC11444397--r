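test_that("prefix enumeration is exhaustive and lexicographic", {
  p5 <- enumeratePrefixes(c("A", "U", "G", "C"), 5L)
  expect_length(p5, 1024L)
  expect_identical(anyDuplicated(p5), 0L)
  expect_identical(enumeratePrefixes(c("A", "C"), 2L), c("AA", "AC", "CA", "CC"))
  expect_identical(enumeratePrefixes(c("A", "C"), 0L), "")
})

test_that("beam width 1 and top-k 1 reproduce greedy decoding on arbitrary toy models", {
  tok <- baseOnlyTokenizer()
  for (seed in 1:5) {
    tbl <- rnalm:::withSeed(seed, {
      ctxs <- as.character(0:4)
      setNames(lapply(ctxs, function(ctx) {
        p <- runif(5); p / sum(p)
      }), ctxs)
    })
    tm <- tableModel(5L, table = tbl, order = 1L)
    g <- generateSequence(tm, tok, "", samplingSpec("greedy", maxNewTokens = 6L))
    b <- generateSequence(tm, tok, "", samplingSpec("beam", beamWidth = 1L, maxNewTokens = 6L))
    k <- generateSequence(tm, tok, "", samplingSpec("topk", topK = 1L, maxNewTokens = 6L))
    expect_identical(as.character(b), as.character(g))
    expect_identical(as.character(k), as.character(g))
  }
})

test_that("beam search finds the argmax joint probability pair on a hand-set model", {
  ## two-step toy: p(a)=0.6, p(b)=0.4, but continuations after a are spread
  ## while b leads to a high-probability EOS: joint argmax differs from greedy
  tok <- baseOnlyTokenizer()
  tm <- tableModel(3L, table = list(
    "0" = c(0.0, 0.6, 0.4),                   # start: a=1 likely
    "1" = c(0.40, 0.35, 0.25),                # after a: spread, EOS likely-ish
    "2" = c(0.95, 0.03, 0.02)), order = 1L)
  ## exhaustive enumeration over all complete paths of <= 2 tokens
  paths <- list(c(1L), c(2L), c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  pOf <- function(ids) {
    ctx <- 0L; lp <- 0
    for (t in ids) { lp <- lp + log(tm@table[[as.character(ctx)]][t + 1L]); ctx <- t }
    lp + log(tm@table[[as.character(ctx)]][1L])  # terminating EOS
  }
  joint <- vapply(paths, pOf, numeric(1))
  bestPath <- paths[[which.max(joint)]]
  got <- generateSequence(tm, tok, "", samplingSpec("beam", beamWidth = 2L, maxNewTokens = 2L))
  expect_identical(as.character(got), decodeTokens(tok, bestPath))
})

test_that("deterministic strategies repeat exactly; top-k repeats under a fixed seed", {
  tok <- fixtureTokenizer()
  m <- fixturePretrainedModel()
  spec <- samplingSpec("greedy", maxNewTokens = 10L)
  g1 <- generateSequence(m, tok, "ACGTA", spec)
  g2 <- generateSequence(m, tok, "ACGTA", spec)
  expect_identical(as.character(g1), as.character(g2))
  sp <- samplingSpec("topk", topK = 8L, maxNewTokens = 10L, seed = 5L)
  t1 <- generateBatch(m, tok, sp, n = 5L)
  t2 <- generateBatch(m, tok, sp, n = 5L)
  expect_identical(as.character(t1), as.character(t2))
})

test_that("top-k sampling converges to greedy as temperature approaches zero", {
  tok <- baseOnlyTokenizer()
  tm <- toyTableModel()
  g <- generateSequence(tm, tok, "", samplingSpec("greedy", maxNewTokens = 6L))
  for (seed in 1:5) {
    cold <- generateSequence(tm, tok, "",
      samplingSpec("topk", topK = 4L, temperature = 1e-4, maxNewTokens = 6L, seed = seed))
    expect_identical(as.character(cold), as.character(g))
  }
})

test_that("unrestricted sampling matches the model distribution (chi-square)", {
  tok <- baseOnlyTokenizer()
  p <- c(0.05, 0.4, 0.25, 0.2, 0.1)            # eos, A, C, G, T
  tm <- tableModel(5L, table = list("0" = p), order = 1L,
                   default = c(1, 0, 0, 0, 0)) # always EOS after first token
  draws <- generateBatch(tm, tok, samplingSpec("topk", topK = 5L, seed = 9L,
                                               maxNewTokens = 1L), n = 5000L)
  firsts <- substr(as.character(draws), 1, 1)
  obs <- table(factor(firsts, levels = c("", "A", "C", "G", "T")))
  exp <- p * 5000
  chi <- sum((as.numeric(obs) - exp)^2 / exp)
  expect_lt(chi, qchisq(0.999, df = 4))
})

test_that("generated strings never contain EOS and prefixes are honoured", {
  tok <- fixtureTokenizer()
  m <- fixturePretrainedModel()
  out <- generateBatch(m, tok, samplingSpec("greedy", maxNewTokens = 6L), prefixLen = 2L)
  expect_length(out, 16L)
  expect_false(any(grepl("[^ACGT]", as.character(out))))
  ## each greedy output starts with its enumerated prefix (U rendered as T)
  prefixes <- chartr("U", "T", enumeratePrefixes(length = 2L))
  expect_equal(unname(substr(as.character(out), 1, 2)), prefixes)
})
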