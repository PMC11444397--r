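## Protein-binding RNA pipeline: curation, the PWM+logistic affinity-scorer
## stand-in, the fine-tune-and-generate experiment and the ablation
## comparison.

#' Curate a binding dataset
#'
#' Deduplicates positives and negatives independently at the identity
#' threshold (default 80%), splits the positives into generator-fine-tuning /
#' scorer-training / test partitions (default 60/30/10) and randomly selects
#' an equivalent count of negatives for the scorer-training and test sets.
#'
#' @param positives positive (binding) sequences.
#' @param negatives negative (background) sequences.
#' @param identityThreshold deduplication identity threshold.
#' @param fractions positive-split fractions (named or not; order is
#'   generator_finetune, scorer_train, test).
#' @param dedup set FALSE to skip deduplication, e.g. for deliberately
#'   redundant fixture sets whose duplication is the point.
#' @param seed integer seed.
#' @return a [BindingDataset-class].
#' @export
curateBindingData <- function(positives, negatives, identityThreshold = 0.8,
                              fractions = c(0.6, 0.3, 0.1), dedup = TRUE,
                              seed = 1L) {
  positives <- asDNA(positives); negatives <- asDNA(negatives)
  if (length(positives) == 0L || length(negatives) == 0L)
    stopf("positives and negatives must be non-empty")
  pos <- if (dedup) deduplicate(positives, identityThreshold) else positives
  neg <- if (dedup) deduplicate(negatives, identityThreshold) else negatives
  fr <- setNames(fractions, c("generator_finetune", "scorer_train", "test"))
  split <- splitCorpus(pos, fr, seed = deriveSeed(seed, "possplit"))
  nNeeded <- length(split$scorer_train) + length(split$test)
  if (length(neg) < nNeeded)
    stopf("insufficient negatives after deduplication: need %d, have %d",
          nNeeded, length(neg))
  idx <- withSeed(deriveSeed(seed, "negpick"), sample.int(length(neg), nNeeded))
  negScorer <- neg[sort(idx[seq_len(length(split$scorer_train))])]
  negTest <- neg[sort(idx[(length(split$scorer_train) + 1L):nNeeded])]
  new("BindingDataset", positives = pos, negatives = neg,
      partitions = c(split, list(neg_scorer_train = negScorer, neg_test = negTest)))
}

pwmConsensus <- function(model) {
  paste0(BASES[apply(model@pwm, 2, which.max)], collapse = "")
}

countWords <- function(seqs, w) {
  tab <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seqs)
    for (word in substring(s, seq_len(max(0L, nchar(s) - w + 1L)), seq(w, nchar(s)))) {
      if (!grepl("[^ACGT]", word))
        tab[[word]] <- (if (is.null(tab[[word]])) 0L else tab[[word]]) + 1L
    }
  unlist(as.list(tab))
}

## Sliding-window max log-odds of a sequence under the PWM.
maxWindowScore <- function(pwm, s) {
  w <- ncol(pwm)
  n <- nchar(s)
  if (n < w) stopf("sequence shorter than the motif width (%d nt)", w)
  ch <- seqChars(s)[[1]]
  idx <- match(ch, BASES)
  best <- -Inf
  for (start in seq_len(n - w + 1L)) {
    ii <- idx[start:(start + w - 1L)]
    if (anyNA(ii)) next                       # ambiguity codes break a window
    sc <- sum(pwm[cbind(ii, seq_len(w))])
    if (sc > best) best <- sc
  }
  if (!is.finite(best)) best <- sum(apply(pwm, 2, min))
  best
}

#' Train the PWM + logistic affinity scorer
#'
#' Estimates a position weight matrix from the most enriched width-w words in
#' the positive set (count-based with pseudocount 1, enrichment measured
#' against the negative word frequencies), converts it to log-odds against
#' the negative-set base composition, and fits a logistic calibration of the
#' best-sliding-window log-odds score on the training labels, so scores land
#' in [0, 1].
#'
#' @param posTrain positive training sequences (>= 50).
#' @param negTrain negative training sequences (>= 50).
#' @param motifWidth motif width w in nt.
#' @param nTopWords number of enriched words aggregated into the PWM.
#' @param seed integer seed (currently only stored; the estimator is
#'   deterministic).
#' @return an [AffinityModel-class].
#' @export
trainAffinityScorer <- function(posTrain, negTrain, motifWidth = 6L,
                                nTopWords = 30L, seed = 1L) {
  posTrain <- asDNA(posTrain); negTrain <- asDNA(negTrain)
  if (length(posTrain) < 50L || length(negTrain) < 50L)
    stopf("need at least 50 sequences per class")
  pseqs <- as.character(posTrain); nseqs <- as.character(negTrain)
  if (identical(sort(pseqs), sort(nseqs)))
    warning("positive and negative classes are identical; scorer will be degenerate",
            call. = FALSE)
  w <- as.integer(motifWidth)
  pc <- countWords(pseqs, w)
  nc <- countWords(nseqs, w)
  words <- union(names(pc), names(nc))
  pcnt <- ifelse(is.na(pc[words]), 0L, pc[words]) + 1
  ncnt <- ifelse(is.na(nc[words]), 0L, nc[words]) + 1
  enrich <- log((pcnt / sum(pcnt)) / (ncnt / sum(ncnt)))
  ## anchor on the single most enriched word, then estimate positional base
  ## frequencies from each positive's closest window to that anchor; this
  ## keeps all stacked windows in the same register (naively stacking several
  ## enriched words mixes phase-shifted fragments of the same motif)
  anchor <- seqChars(words[which.max(enrich)])[[1]]
  pwmCounts <- matrix(1, 4, w, dimnames = list(BASES, NULL))
  for (s in pseqs) {
    n <- nchar(s)
    if (n < w) next
    ch <- seqChars(s)[[1]]
    bestD <- w + 1L; bestStart <- NA_integer_
    for (start in seq_len(n - w + 1L)) {
      win <- ch[start:(start + w - 1L)]
      d <- sum(win != anchor)
      if (d < bestD) { bestD <- d; bestStart <- start }
    }
    if (bestD <= floor(w / 2)) {
      win <- ch[bestStart:(bestStart + w - 1L)]
      ok <- win %in% BASES
      for (j in which(ok)) pwmCounts[win[j], j] <- pwmCounts[win[j], j] + 1
    }
  }
  pwmProb <- sweep(pwmCounts, 2, colSums(pwmCounts), "/")
  baseCounts <- table(factor(unlist(strsplit(nseqs, "", fixed = TRUE)), levels = BASES)) + 1
  background <- as.numeric(baseCounts / sum(baseCounts))
  pwm <- log(pwmProb / background)
  ## logistic calibration on the training labels; a small ridge penalty on
  ## the slope keeps the fit finite when the classes are linearly separable
  ## (unpenalized ML would diverge and collapse scores to a 0/1 step)
  sc <- c(vapply(pseqs, function(s) maxWindowScore(pwm, s), numeric(1)),
          vapply(nseqs, function(s) maxWindowScore(pwm, s), numeric(1)))
  y <- rep(c(1, 0), c(length(pseqs), length(nseqs)))
  penNLL <- function(b) {
    eta <- b[1] + b[2] * sc
    -sum(y * eta - log1p(exp(eta))) + 0.5 * b[2]^2
  }
  fit <- stats::optim(c(0, 1), penNLL, method = "BFGS")
  new("AffinityModel", pwm = pwm, background = background,
      coef = as.numeric(fit$par), motifWidth = w)
}

#' Score binding affinity of sequences
#'
#' Logistic calibration applied to the best sliding-window PWM log-odds;
#' monotone in the window score and always in [0, 1].
#'
#' @param model an [AffinityModel-class].
#' @param x sequences (each at least `motifWidth` nt long).
#' @return numeric vector of affinity scores in [0, 1].
#' @export
scoreAffinity <- function(model, x) {
  seqs <- as.character(asDNA(x))
  sc <- vapply(seqs, function(s) maxWindowScore(model@pwm, s), numeric(1))
  unname(plogis(model@coef[1] + model@coef[2] * sc))
}

#' Fine-tune, generate and evaluate protein-binding RNA
#'
#' The full desk-scale workflow: fine-tunes the pre-trained model on the
#' generator partition of the curated dataset, generates as many sequences as
#' the positive test set holds, scores the generated / positive-test /
#' negative-test groups with the affinity scorer trained on the scorer
#' partitions, and runs a novelty search of the generated sequences against
#' the full positive set.
#'
#' @param pretrained a pre-trained [LanguageModel-class].
#' @param tokenizer the shared [BPETokenizer-class].
#' @param dataset a [BindingDataset-class].
#' @param finetuneEpochs fine-tuning epochs (desk default 10).
#' @param sampling a [samplingSpec()] for generation.
#' @param motifWidth affinity-scorer motif width.
#' @param seed integer seed.
#' @return a list: `model`, `scorer`, `generated`, `affinity` (list of three
#'   score vectors), `novelty` (data.frame), `noveltySummary`, `history`.
#' @export
runBinderExperiment <- function(pretrained, tokenizer, dataset,
                                finetuneEpochs = 10L,
                                sampling = NULL, motifWidth = 6L, seed = 1L) {
  if (is.null(sampling))
    sampling <- samplingSpec(strategy = "topk", topK = 8L,
                             seed = deriveSeed(seed, "gen"))
  ft <- finetuneModel(pretrained, dataset@partitions$generator_finetune,
                      tokenizer, epochs = finetuneEpochs,
                      seed = deriveSeed(seed, "ft"))
  nGen <- length(dataset@partitions$test)
  generated <- generateBatch(ft$model, tokenizer, sampling, n = nGen)
  scorer <- trainAffinityScorer(dataset@partitions$scorer_train,
                                dataset@partitions$neg_scorer_train,
                                motifWidth = motifWidth,
                                seed = deriveSeed(seed, "scorer"))
  minLen <- scorer@motifWidth
  keep <- Biostrings::width(generated) >= minLen
  affinity <- list(
    generated = if (any(keep)) scoreAffinity(scorer, generated[keep]) else numeric(0),
    positive_test = scoreAffinity(scorer, dataset@partitions$test),
    negative_test = scoreAffinity(scorer, dataset@partitions$neg_test))
  novelty <- noveltySearch(generated, dataset@positives,
                           seed = deriveSeed(seed, "novelty"))
  list(model = ft$model, scorer = scorer, generated = generated,
       affinity = affinity, novelty = novelty,
       noveltySummary = noveltySummary(novelty), history = ft$history)
}

#' Ablation: scratch-trained model vs fine-tuned pre-trained model
#'
#' Trains the same architecture from random initialisation on the
#' generator partition (with early stopping on validation loss, patience 3),
#' fine-tunes the pre-trained model on the same data, generates equal-sized
#' batches from both, and compares their novelty against the full positive
#' set: percentage of generated sequences identical to a known positive and
#' percentage with no significant hit.
#'
#' @param pretrained a pre-trained [LanguageModel-class].
#' @param tokenizer the shared tokenizer.
#' @param dataset a [BindingDataset-class].
#' @param scratchEpochs maximum epochs for the scratch model (early stopping
#'   usually ends training sooner).
#' @param scratchBatchSize batch size for scratch training (small, so a tiny
#'   corpus still yields several optimizer steps per epoch).
#' @param finetuneEpochs fine-tuning epochs for the pre-trained model.
#' @param nGenerate generated sequences per model.
#' @param sampling a [samplingSpec()] for generation.
#' @param seed integer seed.
#' @return a list with `table` (data.frame rows ablation / fine-tuned,
#'   columns identical_pct / nohit_pct) and the two novelty data.frames.
#' @export
ablationCompare <- function(pretrained, tokenizer, dataset,
                            scratchEpochs = 400L, finetuneEpochs = 10L,
                            nGenerate = 50L, sampling = NULL,
                            scratchBatchSize = 4L, seed = 1L) {
  if (is.null(sampling))
    sampling <- samplingSpec(strategy = "topk", topK = 8L,
                             seed = deriveSeed(seed, "gen"))
  ftData <- dataset@partitions$generator_finetune
  valSplit <- splitCorpus(ftData, c(train = 0.9, val = 0.1),
                          seed = deriveSeed(seed, "valsplit"))
  scratch <- buildModel(new("ModelConfig",
    nLayers = pretrained@config@nLayers, dModel = pretrained@config@dModel,
    nHeads = pretrained@config@nHeads, contextLen = pretrained@config@contextLen,
    vocabSize = pretrained@config@vocabSize, initStd = pretrained@config@initStd,
    seed = deriveSeed(seed, "scratchinit")))
  stream <- makeTrainingStream(valSplit$train, tokenizer,
                               scratch@config@contextLen,
                               seed = deriveSeed(seed, "scratchstream"))
  cfgScratch <- trainConfig(schedule = constantSchedule(1e-3),
                            batchSize = scratchBatchSize,
                            epochs = scratchEpochs, earlyStopPatience = 3L,
                            seed = deriveSeed(seed, "scratchtrain"))
  scratchFit <- trainModel(scratch, stream, cfgScratch, tokenizer = tokenizer,
                           valRecords = valSplit$val)
  ft <- finetuneModel(pretrained, ftData, tokenizer, epochs = finetuneEpochs,
                      seed = deriveSeed(seed, "ft"))
  genOf <- function(model, tag) {
    sp <- sampling; sp$seed <- deriveSeed(seed, tag)
    generateBatch(model, tokenizer, sp, n = nGenerate)
  }
  genScratch <- genOf(scratchFit$model, "genscratch")
  genFt <- genOf(ft$model, "genft")
  novScratch <- noveltySearch(genScratch, dataset@positives,
                              seed = deriveSeed(seed, "novS"))
  novFt <- noveltySearch(genFt, dataset@positives, seed = deriveSeed(seed, "novF"))
  sS <- noveltySummary(novScratch); sF <- noveltySummary(novFt)
  tab <- data.frame(
    model = c("ablation", "fine-tuned"),
    identical_pct = c(sS[["identical_pct"]], sF[["identical_pct"]]),
    nohit_pct = c(sS[["nohit_pct"]], sF[["nohit_pct"]]))
  list(table = tab, noveltyScratch = novScratch, noveltyFinetuned = novFt,
       scratchHistory = scratchFit$history, finetunedHistory = ft$history)
}
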