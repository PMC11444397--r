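test_that("learning-rate schedule is piecewise linear with the documented anchors", {
  sch <- lrSchedule(peakLR = 1e-3, finalLR = 1e-4, warmupEpochs = 0.67,
                    totalEpochs = 12L, stepsPerEpoch = 100L)
  expect_identical(lrAtStep(sch, 0L), 0)
  expect_equal(lrAtStep(sch, sch$warmupSteps), 1e-3)
  expect_equal(lrAtStep(sch, sch$totalSteps), 1e-4)
  ## continuity and maximum at warmup end
  steps <- 0:sch$totalSteps
  lrs <- lrAtStep(sch, steps)
  expect_equal(max(lrs), 1e-3)
  expect_lt(max(abs(diff(lrs)[-sch$warmupSteps])), 2e-5)
  expect_error(lrAtStep(sch, -1L), "range")
  ## fine-tuning schedule: constant everywhere
  cs <- constantSchedule(1e-4)
  expect_identical(lrAtStep(cs, 0L), 1e-4)
  expect_identical(lrAtStep(cs, 10000L), 1e-4)
  expect_error(lrSchedule(peakLR = 1e-3, finalLR = 2e-3), "finalLR")
  expect_error(trainConfig(adamBeta1 = 1.2), "betas")
})

test_that("training stream conserves tokens and is seed-deterministic", {
  tok <- baseOnlyTokenizer()
  x <- c(a = "ACG", b = "TTT")
  st <- makeTrainingStream(x, tok, contextLen = 8L, seed = 1L)
  expect_identical(dim(st$blocks), c(1L, 8L))
  expect_identical(sum(st$lossMask), 8L)       # 6 nt + 2 EOS
  expect_identical(sum(st$blocks[st$lossMask] == eosId(tok)), 2L)
  ## larger corpus: sum of real tokens = sum sequence tokens + n EOS
  x2 <- vapply(1:20, function(i) randomSeq(15), character(1))
  st2 <- makeTrainingStream(x2, tok, contextLen = 16L, seed = 2L)
  expect_identical(sum(st2$lossMask), 20L * 15L + 20L)
  st2b <- makeTrainingStream(x2, tok, contextLen = 16L, seed = 2L)
  expect_identical(st2$blocks, st2b$blocks)
})

test_that("an untrained model has validation perplexity near the vocabulary size", {
  tok <- baseOnlyTokenizer()
  cfg <- modelConfig(nLayers = 1L, dModel = 16L, nHeads = 2L,
                     contextLen = 16L, vocabSize = vocabSize(tok), seed = 1L)
  m <- buildModel(cfg)
  m@params$wte[] <- 0                          # exactly uniform
  nll <- validationNLL(m, tok, vapply(1:10, function(i) randomSeq(12), character(1)))
  expect_equal(exp(nll), vocabSize(tok), tolerance = 1e-6)
})

test_that("a short training run reduces the loss and is reproducible", {
  tok <- baseOnlyTokenizer()
  x <- rep("ACGTACGTACGT", 50)
  cfg <- modelConfig(nLayers = 1L, dModel = 16L, nHeads = 2L,
                     contextLen = 16L, vocabSize = vocabSize(tok), seed = 6L)
  st <- makeTrainingStream(x, tok, cfg@contextLen, seed = 1L)
  tc <- trainConfig(epochs = 8L, batchSize = 8L, seed = 3L)
  fit1 <- trainModel(buildModel(cfg), st, tc, tokenizer = tok, valRecords = x[1:5])
  expect_lt(tail(fit1$history$train_nll, 1), fit1$history$train_nll[1])
  expect_equal(fit1$history$val_ppl, exp(fit1$history$val_nll))
  ## bitwise reproducibility of the whole run
  fit2 <- trainModel(buildModel(cfg), st, tc, tokenizer = tok, valRecords = x[1:5])
  expect_identical(fit1$model@params, fit2$model@params)
  expect_identical(fit1$history, fit2$history)
})

test_that("early stopping returns the best-validation checkpoint", {
  tok <- baseOnlyTokenizer()
  ## train on one pattern, validate on a conflicting one: validation
  ## deteriorates as training progresses, so patience must trigger
  x <- rep("ACACACACACAC", 40)
  val <- rep("GTGTGTGTGTGT", 5)
  cfg <- modelConfig(nLayers = 1L, dModel = 16L, nHeads = 2L,
                     contextLen = 16L, vocabSize = vocabSize(tok), seed = 2L)
  st <- makeTrainingStream(x, tok, cfg@contextLen, seed = 1L)
  tc <- trainConfig(epochs = 30L, batchSize = 8L, earlyStopPatience = 2L, seed = 3L)
  fit <- trainModel(buildModel(cfg), st, tc, tokenizer = tok, valRecords = val)
  expect_lt(nrow(fit$history), 30L)            # stopped early
  best <- which.min(fit$history$val_nll)
  returned <- validationNLL(fit$model, tok, val)
  expect_equal(returned, fit$history$val_nll[best], tolerance = 1e-9)
})

test_that("fine-tuning runs at constant LR and zero epochs is the identity", {
  tok <- fixtureTokenizer()
  model <- fixturePretrainedModel()
  ft0 <- finetuneModel(model, c("ACGTACGT"), tok, epochs = 0L)
  expect_identical(ft0$model@params, model@params)
  sets <- fixtureBindingSets(nPos = 40L, nNeg = 5L, seed = 51L)
  ft <- finetuneModel(model, sets$positives[1:30], tok, epochs = 3L, seed = 4L)
  expect_true(all(ft$history$lr == 1e-4))
  ## fine-tuning on motif-implanted positives reduces their held-out NLL
  before <- validationNLL(model, tok, sets$positives[31:40])
  after <- validationNLL(ft$model, tok, sets$positives[31:40])
  expect_lt(after, before)
})
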