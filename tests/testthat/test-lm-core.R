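test_that("initialisation follows the documented scheme deterministically", {
  cfg <- modelConfig(nLayers = 1L, dModel = 32L, nHeads = 4L,
                     contextLen = 16L, vocabSize = 512L, seed = 3L)
  m <- buildModel(cfg)
  ## embedding entries ~ N(0, 0.02): sample s.d. within 10% over 16k entries
  expect_lt(abs(sd(m@params$wte) - 0.02) / 0.02, 0.1)
  m2 <- buildModel(cfg)
  expect_identical(m@params, m2@params)
  expect_error(modelConfig(dModel = 6L, nHeads = 4L), "divisible")
})

test_that("parameter count equals an explicit shape enumeration", {
  cfg <- modelConfig(nLayers = 2L, dModel = 16L, nHeads = 2L,
                     contextLen = 12L, vocabSize = 64L, seed = 1L)
  m <- buildModel(cfg)
  d <- 16L; V <- 64L; ctx <- 12L; dff <- 64L
  perLayer <- 2 * d +                 # ln1
    4 * (d * d + d) +                 # q, k, v, o projections + biases
    2 * d +                           # ln2
    d * dff + dff + dff * d + d       # mlp
  expected <- V * d + ctx * d + 2L * perLayer + 2L * d
  expect_identical(countParameters(m), as.integer(expected))
  ## embedding alone contributes V x d
  expect_identical(length(m@params$wte), 64L * 16L)
  ## strictly more parameters with more layers
  m3 <- buildModel(modelConfig(nLayers = 3L, dModel = 16L, nHeads = 2L,
                               contextLen = 12L, vocabSize = 64L))
  expect_gt(countParameters(m3), countParameters(m))
})

test_that("forward log-probabilities are normalised, causal and uniform for zeroed output", {
  cfg <- modelConfig(nLayers = 2L, dModel = 32L, nHeads = 4L,
                     contextLen = 16L, vocabSize = 8L, seed = 5L)
  m <- buildModel(cfg)
  lp <- forwardLogProbs(m, c(0L, 1L, 2L, 3L))
  expect_equal(rowSums(exp(lp)), rep(1, 4), tolerance = 1e-5)
  ## causality: changing position 4 leaves rows 1..3 unchanged
  lp2 <- forwardLogProbs(m, c(0L, 1L, 2L, 7L))
  expect_equal(lp[1:3, ], lp2[1:3, ], tolerance = 1e-12)
  ## zeroed (tied) output projection: every row exactly uniform
  m0 <- m; m0@params$wte[] <- 0
  lp0 <- forwardLogProbs(m0, c(0L, 3L))
  expect_equal(as.vector(lp0), rep(-log(8), 16), tolerance = 1e-9)
  expect_error(forwardLogProbs(m, c(0L, 99L)), "range")
  expect_error(forwardLogProbs(m, rep(0L, 17)), "context")
})

test_that("sequence NLL matches gathered forward log-probabilities and the uniform analytic value", {
  cfg <- modelConfig(nLayers = 1L, dModel = 16L, nHeads = 2L,
                     contextLen = 12L, vocabSize = 6L, seed = 2L)
  m <- buildModel(cfg)
  ids <- c(0L, 3L, 1L, 5L, 2L)
  lp <- forwardLogProbs(m, ids)
  manual <- -sum(lp[cbind(1:4, ids[-1] + 1L)])
  expect_equal(sequenceNLL(m, ids), manual, tolerance = 1e-10)
  res <- sequenceNLL(m, ids, perToken = TRUE)
  expect_equal(res$perToken, res$total / 4)
  ## uniform model: per-token NLL = ln V
  m0 <- m; m0@params$wte[] <- 0
  expect_equal(sequenceNLL(m0, ids, perToken = TRUE)$perToken, log(6),
               tolerance = 1e-9)
  expect_error(sequenceNLL(m, 0L), "at least 2")
})

test_that("chain rule: probabilities of all two-token continuations sum to one", {
  cfg <- modelConfig(nLayers = 1L, dModel = 16L, nHeads = 2L,
                     contextLen = 8L, vocabSize = 4L, seed = 8L)
  m <- buildModel(cfg)
  prefix <- c(0L, 2L)
  tot <- 0
  for (a in 0:3) for (b in 0:3) {
    ids <- c(prefix, a, b)
    lp <- forwardLogProbs(m, ids)
    tot <- tot + exp(lp[2, a + 1L] + lp[3, b + 1L])
  }
  expect_equal(tot, 1, tolerance = 1e-6)
})

test_that("analytic gradients agree with central finite differences", {
  cfg <- modelConfig(nLayers = 1L, dModel = 8L, nHeads = 2L,
                     contextLen = 8L, vocabSize = 6L, seed = 7L)
  m <- buildModel(cfg)
  ids <- matrix(c(0L, 1L, 2L, 3L, 4L, 5L, 1L, 2L), nrow = 1)
  tg <- cbind(ids[, -1, drop = FALSE], NA)
  lg <- rnalm:::lmLossGrad(m@params, cfg, ids, tg)
  eps <- 1e-5
  probe <- list(
    list(get = function(p) p$wte[3, 2],
         set = function(p, v) { p$wte[3, 2] <- v; p },
         ana = lg$grads$wte[3, 2]),
    list(get = function(p) p$layers[[1]]$wq[4, 3],
         set = function(p, v) { p$layers[[1]]$wq[4, 3] <- v; p },
         ana = lg$grads$layers[[1]]$wq[4, 3]),
    list(get = function(p) p$layers[[1]]$w2[17, 3],
         set = function(p, v) { p$layers[[1]]$w2[17, 3] <- v; p },
         ana = lg$grads$layers[[1]]$w2[17, 3]),
    list(get = function(p) p$lnfg[5],
         set = function(p, v) { p$lnfg[5] <- v; p },
         ana = lg$grads$lnfg[5]))
  for (pr in probe) {
    v0 <- pr$get(m@params)
    up <- rnalm:::lmLossGrad(pr$set(m@params, v0 + eps), cfg, ids, tg)$loss
    dn <- rnalm:::lmLossGrad(pr$set(m@params, v0 - eps), cfg, ids, tg)$loss
    expect_equal(pr$ana, (up - dn) / (2 * eps), tolerance = 1e-5)
  }
})

test_that("checkpoints round-trip through save/load", {
  cfg <- modelConfig(nLayers = 1L, dModel = 16L, nHeads = 2L,
                     contextLen = 8L, vocabSize = 6L, seed = 4L)
  m <- buildModel(cfg)
  tmp <- tempfile(fileext = ".rds")
  saveModel(m, tmp)
  back <- loadModel(tmp)
  expect_identical(back@params, m@params)
  expect_equal(forwardLogProbs(back, c(0L, 1L)), forwardLogProbs(m, c(0L, 1L)))
})
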