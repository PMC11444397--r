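## Training: learning-rate schedule, EOS-delimited training stream, Adam
## loop with optional early stopping, and the fine-tuning entry point.

#' Warmup + linear-decay learning-rate schedule
#'
#' Linear warmup from 0 to `peakLR` over the first `warmupEpochs` of
#' training, then linear decay from `peakLR` to `finalLR` over the remaining
#' steps. The defaults (peak 1e-3, final 1e-4, warmup 0.67 of an epoch) are
#' the pre-training recipe; fine-tuning uses [constantSchedule()].
#'
#' @param peakLR learning rate at the end of warmup.
#' @param finalLR learning rate at the final step.
#' @param warmupEpochs warmup duration in (possibly fractional) epochs.
#' @param totalEpochs total training epochs.
#' @param stepsPerEpoch optimizer steps per epoch.
#' @return an `lr_schedule` object usable with [lrAtStep()].
#' @export
lrSchedule <- function(peakLR = 1e-3, finalLR = 1e-4, warmupEpochs = 0.67,
                       totalEpochs = 12L, stepsPerEpoch = 100L) {
  if (finalLR <= 0 || finalLR > peakLR) stopf("need 0 < finalLR <= peakLR")
  if (warmupEpochs < 0 || warmupEpochs >= totalEpochs)
    stopf("need 0 <= warmupEpochs < totalEpochs")
  structure(list(peakLR = peakLR, finalLR = finalLR,
                 warmupSteps = round(warmupEpochs * stepsPerEpoch),
                 totalSteps = as.integer(totalEpochs) * as.integer(stepsPerEpoch)),
            class = "lr_schedule")
}

#' Constant learning-rate schedule
#' @param lr the constant learning rate (fine-tuning default 1e-4).
#' @return an `lr_schedule` object.
#' @export
constantSchedule <- function(lr = 1e-4) {
  structure(list(lr = lr), class = c("constant_schedule", "lr_schedule"))
}

#' Learning rate at an optimizer step
#'
#' Piecewise linear: 0 at step 0, `peakLR` at the last warmup step, `finalLR`
#' at the final step. Constant schedules return their rate everywhere.
#'
#' @param schedule an [lrSchedule()] or [constantSchedule()].
#' @param step step index, 0 to total steps.
#' @return the learning rate.
#' @export
lrAtStep <- function(schedule, step) {
  if (inherits(schedule, "constant_schedule")) return(schedule$lr)
  if (any(step < 0 | step > schedule$totalSteps)) stopf("step out of range")
  w <- schedule$warmupSteps
  ifelse(step <= w,
         if (w > 0) schedule$peakLR * step / w else schedule$peakLR,
         schedule$peakLR + (schedule$finalLR - schedule$peakLR) *
           (step - w) / (schedule$totalSteps - w))
}

#' Training configuration
#'
#' @param schedule an `lr_schedule` (NULL = build the warmup/decay default
#'   once steps-per-epoch is known).
#' @param batchSize sequences-of-blocks per optimizer step.
#' @param epochs training epochs.
#' @param adamBeta1,adamBeta2 Adam moment decay rates.
#' @param clipNorm global gradient-norm clip (NULL disables).
#' @param earlyStopPatience stop after this many epochs without validation
#'   improvement and return the best-validation checkpoint (NULL disables).
#' @param seed seed controlling block shuffling.
#' @return a `train_config` list.
#' @export
trainConfig <- function(schedule = NULL, batchSize = 16L, epochs = 4L,
                        adamBeta1 = 0.9, adamBeta2 = 0.999, clipNorm = 1.0,
                        earlyStopPatience = NULL, seed = 1L) {
  if (adamBeta1 <= 0 || adamBeta1 >= 1 || adamBeta2 <= 0 || adamBeta2 >= 1)
    stopf("Adam betas must lie in (0, 1)")
  structure(list(schedule = schedule, batchSize = as.integer(batchSize),
                 epochs = as.integer(epochs), adamBeta1 = adamBeta1,
                 adamBeta2 = adamBeta2, clipNorm = clipNorm,
                 earlyStopPatience = earlyStopPatience, seed = as.integer(seed)),
            class = "train_config")
}

#' Build the EOS-delimited training stream
#'
#' Sequences are encoded, each terminated by EOS, concatenated in a seeded
#' order and chunked into `contextLen`-token blocks. The final partial block
#' is filled with EOS, and the fill positions are excluded from the loss, so
#' every real token of every sequence contributes to the objective exactly
#' once per epoch.
#'
#' @param x sequences.
#' @param tokenizer a [BPETokenizer-class].
#' @param contextLen block length in tokens.
#' @param seed seed for the concatenation order.
#' @return a list with `blocks` (nBlocks x contextLen id matrix), `lossMask`
#'   (logical matrix marking real-token targets) and `nTokens` bookkeeping.
#' @export
makeTrainingStream <- function(x, tokenizer, contextLen, seed = 1L) {
  seqs <- as.character(asDNA(x))
  enc <- encodeTokens(tokenizer, seqs, addEos = TRUE)
  ord <- withSeed(seed, sample.int(length(enc)))
  flat <- unlist(enc[ord], use.names = FALSE)
  nReal <- length(flat)
  nBlocks <- ceiling(nReal / contextLen)
  pad <- nBlocks * contextLen - nReal
  real <- c(rep(TRUE, nReal), rep(FALSE, pad))
  flat <- c(flat, rep(eosId(tokenizer), pad))
  blocks <- matrix(flat, nrow = nBlocks, ncol = contextLen, byrow = TRUE)
  lossMask <- matrix(real, nrow = nBlocks, ncol = contextLen, byrow = TRUE)
  list(blocks = blocks, lossMask = lossMask,
       nTokens = nReal, nSequences = length(enc))
}

## Targets for a block matrix: within-block next-token prediction. Position
## t predicts position t+1; the last position of each block has no target.
blockTargets <- function(blocks, lossMask) {
  L <- ncol(blocks)
  tg <- cbind(blocks[, -1, drop = FALSE], NA_integer_)
  tg[, L] <- NA_integer_
  tg[!cbind(lossMask[, -1, drop = FALSE], FALSE)] <- NA_integer_
  tg
}

adamInit <- function(params) {
  zero <- function(nm, v) v * 0
  list(m = paramWalk(params, zero), v = paramWalk(params, zero), t = 0L)
}

adamStep <- function(params, grads, state, lr, b1, b2, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  upd <- function(nm, p) {
    g <- getParam(grads, nm)
    m <- b1 * getParam(state$m, nm) + (1 - b1) * g
    v <- b2 * getParam(state$v, nm) + (1 - b2) * g * g
    state$m <<- setParam(state$m, nm, m)
    state$v <<- setParam(state$v, nm, v)
    mhat <- m / (1 - b1^t)
    vhat <- v / (1 - b2^t)
    p - lr * mhat / (sqrt(vhat) + eps)
  }
  params <- paramWalk(params, upd)
  list(params = params, state = state)
}

getParam <- function(params, nm) {
  if (startsWith(nm, "L")) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    params$layers[[as.integer(substring(parts[1], 2))]][[parts[2]]]
  } else params[[nm]]
}

setParam <- function(params, nm, value) {
  if (startsWith(nm, "L")) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    params$layers[[as.integer(substring(parts[1], 2))]][[parts[2]]] <- value
  } else params[[nm]] <- value
  params
}

#' Mean per-token validation NLL over a set of sequences
#'
#' Scores the sequences under the same convention as training: EOS-delimited
#' concatenation chunked into context-length blocks, mean NLL over all real
#' target tokens. Perplexity is `exp` of this value.
#'
#' @param model a [LanguageModel-class].
#' @param tokenizer tokenizer used for encoding.
#' @param x sequences.
#' @param seed block-order seed (the value does not affect the mean; it fixes
#'   the deterministic chunk layout).
#' @return mean per-token NLL in nats.
#' @export
validationNLL <- function(model, tokenizer, x, seed = 0L) {
  stream <- makeTrainingStream(x, tokenizer, model@config@contextLen, seed = seed)
  streamNLL(model, stream)
}

## Mean per-token NLL of a prepared stream (no gradients).
streamNLL <- function(model, stream) {
  targets <- blockTargets(stream$blocks, stream$lossMask)
  tot <- 0; n <- 0L
  for (b in seq_len(nrow(stream$blocks))) {
    tg <- targets[b, ]
    sel <- which(!is.na(tg))
    if (length(sel) == 0L) next
    lp <- logSoftmaxRows(
      lmForwardCore(model@params, model@config,
                    stream$blocks[b, , drop = FALSE])$logits)
    tot <- tot - sum(lp[cbind(sel, tg[sel] + 1L)])
    n <- n + length(sel)
  }
  tot / n
}

#' Train a language model
#'
#' Minimises the per-token negative log-likelihood with Adam under the given
#' learning-rate schedule, with global-norm gradient clipping (default 1.0).
#' History records train NLL, validation NLL and validation perplexity
#' (`exp(per-token NLL)`) per epoch. With `earlyStopPatience` set, training
#' stops after that many epochs without validation improvement and the
#' best-validation checkpoint is returned; otherwise the final model is
#' returned. A non-finite loss aborts with a diagnostic.
#'
#' @param model a [LanguageModel-class] (its weights are the starting point).
#' @param stream a [makeTrainingStream()] result.
#' @param config a [trainConfig()].
#' @param tokenizer tokenizer (needed for validation scoring).
#' @param valRecords optional validation sequences.
#' @param maxSteps optional hard cap on total optimizer steps.
#' @return list with `model`, `history` (data.frame: epoch, step, lr,
#'   train_nll, val_nll, val_ppl) and `bestEpoch`.
#' @export
trainModel <- function(model, stream, config, tokenizer = NULL,
                       valRecords = NULL, maxSteps = NULL) {
  params <- model@params
  cfg <- model@config
  nBlocks <- nrow(stream$blocks)
  stepsPerEpoch <- max(1L, ceiling(nBlocks / config$batchSize))
  schedule <- config$schedule
  if (is.null(schedule))
    schedule <- lrSchedule(totalEpochs = config$epochs, stepsPerEpoch = stepsPerEpoch)
  state <- adamInit(params)
  targetsAll <- blockTargets(stream$blocks, stream$lossMask)
  lrNow <- function(step)
    if (inherits(schedule, "constant_schedule")) schedule$lr
    else lrAtStep(schedule, min(step, schedule$totalSteps))
  history <- data.frame()
  best <- list(val = Inf, params = params, epoch = 0L)
  sinceBest <- 0L
  step <- 0L
  done <- FALSE
  for (epoch in seq_len(config$epochs)) {
    ord <- withSeed(deriveSeed(config$seed, paste0("epoch", epoch)), sample.int(nBlocks))
    epochLoss <- 0; epochSteps <- 0L
    for (s in seq_len(stepsPerEpoch)) {
      idx <- ord[((s - 1L) * config$batchSize + 1L):min(s * config$batchSize, nBlocks)]
      idx <- idx[!is.na(idx)]
      if (length(idx) == 0L) break
      ids <- stream$blocks[idx, , drop = FALSE]
      tg <- targetsAll[idx, , drop = FALSE]
      if (all(is.na(tg))) next
      lg <- lmLossGrad(params, cfg, ids, tg)
      if (!is.finite(lg$loss))
        stopf("training diverged (non-finite loss) at step %d", step + 1L)
      grads <- lg$grads
      if (!is.null(config$clipNorm)) {
        gn <- gradGlobalNorm(grads)
        if (gn > config$clipNorm) {
          sc <- config$clipNorm / gn
          grads <- paramWalk(grads, function(nm, v) v * sc)
        }
      }
      step <- step + 1L
      lr <- lrNow(step)
      ad <- adamStep(params, grads, state, lr, config$adamBeta1, config$adamBeta2)
      params <- ad$params; state <- ad$state
      epochLoss <- epochLoss + lg$loss; epochSteps <- epochSteps + 1L
      if (!is.null(maxSteps) && step >= maxSteps) { done <- TRUE; break }
    }
    valNLL <- NA_real_
    if (!is.null(valRecords) && !is.null(tokenizer)) {
      tmp <- new("LanguageModel", config = cfg, params = params)
      valNLL <- validationNLL(tmp, tokenizer, valRecords)
      if (valNLL < best$val) {
        best <- list(val = valNLL, params = params, epoch = epoch)
        sinceBest <- 0L
      } else sinceBest <- sinceBest + 1L
    }
    history <- rbind(history, data.frame(
      epoch = epoch, step = step, lr = lrNow(step),
      train_nll = if (epochSteps) epochLoss / epochSteps else NA_real_,
      val_nll = valNLL, val_ppl = exp(valNLL)))
    if (!is.null(config$earlyStopPatience) && !is.na(valNLL) &&
        sinceBest >= config$earlyStopPatience) { done <- TRUE }
    if (done) break
  }
  finalParams <- if (!is.null(config$earlyStopPatience) && is.finite(best$val))
    best$params else params
  list(model = new("LanguageModel", config = cfg, params = finalParams),
       history = history, bestEpoch = best$epoch)
}

#' Fine-tune a model on a smaller corpus
#'
#' The same loop as [trainModel()] with a constant learning rate (default
#' 1e-4, no warmup or decay). Zero epochs return the model unchanged.
#'
#' @param model a trained [LanguageModel-class].
#' @param x fine-tuning sequences.
#' @param tokenizer tokenizer shared with pre-training.
#' @param epochs fine-tuning epochs.
#' @param lr constant learning rate.
#' @param valRecords optional validation sequences.
#' @param config optional [trainConfig()] (its schedule is forced constant).
#' @param seed stream/shuffle seed.
#' @return as [trainModel()].
#' @export
finetuneModel <- function(model, x, tokenizer, epochs = 5L, lr = 1e-4,
                          valRecords = NULL, config = NULL, seed = 1L) {
  if (epochs == 0L)
    return(list(model = model, history = data.frame(), bestEpoch = 0L))
  if (is.null(config))
    config <- trainConfig(schedule = constantSchedule(lr), epochs = epochs, seed = seed)
  config$schedule <- constantSchedule(lr)
  config$epochs <- as.integer(epochs)
  stream <- makeTrainingStream(x, tokenizer, model@config@contextLen, seed = seed)
  trainModel(model, stream, config, tokenizer = tokenizer, valRecords = valRecords)
}

#' Write a training history as TSV
#' @param history the history data.frame from [trainModel()].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeHistoryTSV <- function(history, path) {
  write.table(history, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
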