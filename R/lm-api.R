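## User-facing model API.

#' Create a model configuration
#'
#' The desk-scale default (2 layers, d_model 64, 4 heads, context 64) keeps a
#' full pure-R training run in the minutes range on one CPU while exercising
#' every architectural component; [paperScaleConfig()] records the
#' publication-scale preset, which this package never instantiates.
#'
#' @param nLayers number of decoder layers.
#' @param dModel model dimension (divisible by `nHeads`).
#' @param nHeads attention heads.
#' @param contextLen context window in tokens.
#' @param vocabSize vocabulary size.
#' @param initStd Gaussian s.d. for embedding/positional weights.
#' @param seed seed for weight initialisation.
#' @return a [ModelConfig-class].
#' @export
modelConfig <- function(nLayers = 2L, dModel = 64L, nHeads = 4L,
                        contextLen = 64L, vocabSize = 64L,
                        initStd = 0.02, seed = 1L) {
  new("ModelConfig", nLayers = as.integer(nLayers), dModel = as.integer(dModel),
      nHeads = as.integer(nHeads), contextLen = as.integer(contextLen),
      vocabSize = as.integer(vocabSize), initStd = initStd, seed = as.integer(seed))
}

#' Publication-scale configuration preset (recorded, never trained here)
#'
#' 24 layers, model dimension 1280, context 1024, vocabulary 1024 — the
#' configuration of the full-scale model this package re-implements at desk
#' scale. Provided for reference and for parameter-count inspection only.
#'
#' @return a [ModelConfig-class].
#' @export
paperScaleConfig <- function() {
  modelConfig(nLayers = 24L, dModel = 1280L, nHeads = 20L,
              contextLen = 1024L, vocabSize = 1024L)
}

#' Build (initialise) a causal decoder language model
#'
#' Linear-layer weights use Kaiming (He) initialisation; token embedding and
#' positional weights are Gaussian with mean 0 and s.d. `initStd` (default
#' 0.02); LayerNorm gains/biases start at 1/0; all biases at 0. The token
#' embedding is tied with the output projection. Deterministic given
#' `config@seed`.
#'
#' @param config a [ModelConfig-class].
#' @return a [LanguageModel-class].
#' @export
buildModel <- function(config) {
  validObject(config)
  new("LanguageModel", config = config, params = initParams(config))
}

#' Count trainable parameters
#'
#' Sum of all trainable weight entries; the tied embedding/output matrix is
#' counted once.
#'
#' @param model a [LanguageModel-class].
#' @return an integer count.
#' @export
countParameters <- function(model) {
  tot <- 0
  invisible(paramWalk(model@params, function(nm, v) { tot <<- tot + length(v); v }))
  as.integer(tot)
}

#' Next-token log-probability matrix for a token sequence
#'
#' Runs the model over `ids` and returns the L x V matrix of natural-log
#' next-token distributions; row t conditions only on positions 1..t
#' (causality), and every row is normalised (logsumexp 0 within 1e-5).
#'
#' @param model a [LanguageModel-class].
#' @param ids integer vector of 0-based token ids, 1 <= length <= context.
#' @return an L x V matrix of log-probabilities.
#' @export
forwardLogProbs <- function(model, ids) {
  ids <- as.integer(ids)
  if (length(ids) < 1L) stopf("need at least one token")
  fw <- lmForwardCore(model@params, model@config, matrix(ids, nrow = 1))
  logSoftmaxRows(fw$logits)
}

#' Negative log-likelihood of a token sequence
#'
#' `-sum_{i=2..L} log p(x_i | x_<i)` in nats: every token after the first is
#' scored given its prefix. To score all tokens of a sequence, prepend the
#' EOS id (the convention used during training and generation).
#'
#' @param model a [LanguageModel-class].
#' @param ids integer vector of 0-based token ids, length >= 2.
#' @param perToken also return the per-token mean.
#' @return total NLL in nats, or a list with `total` and `perToken` when
#'   `perToken = TRUE`.
#' @export
sequenceNLL <- function(model, ids, perToken = FALSE) {
  ids <- as.integer(ids)
  L <- length(ids)
  if (L < 2L) stopf("sequence NLL needs at least 2 tokens")
  lp <- forwardLogProbs(model, ids)
  picked <- lp[cbind(seq_len(L - 1L), ids[-1] + 1L)]
  total <- -sum(picked)
  if (perToken) list(total = total, perToken = total / (L - 1L)) else total
}

#' @describeIn nextTokenLogProbs transformer forward pass on the context.
#' @export
setMethod("nextTokenLogProbs", "LanguageModel", function(model, ids) {
  lp <- forwardLogProbs(model, ids)
  lp[nrow(lp), ]
})

#' Construct a hand-specified toy next-token model
#'
#' @param vocabSize vocabulary size V (id 0 = EOS).
#' @param table named list mapping comma-joined context ids (the last `order`
#'   ids of the context) to length-V probability vectors.
#' @param order how many trailing context ids form the lookup key.
#' @param default fallback distribution (uniform if NULL).
#' @return a [TableModel-class].
#' @export
tableModel <- function(vocabSize, table = list(), order = 1L, default = NULL) {
  if (is.null(default)) default <- rep(1 / vocabSize, vocabSize)
  stopifnot(length(default) == vocabSize, abs(sum(default) - 1) < 1e-9)
  for (p in table) stopifnot(length(p) == vocabSize, abs(sum(p) - 1) < 1e-9)
  new("TableModel", vocabSize = as.integer(vocabSize), eosId = 0L,
      table = table, order = as.integer(order), default = as.numeric(default))
}

#' @describeIn nextTokenLogProbs table lookup keyed on the trailing context.
#' @export
setMethod("nextTokenLogProbs", "TableModel", function(model, ids) {
  key <- if (model@order == 0L) "" else
    paste(tail(ids, model@order), collapse = ",")
  p <- model@table[[key]]
  if (is.null(p)) p <- model@default
  log(p)
})

#' Save / load a model checkpoint
#'
#' The checkpoint stores the configuration and the flat weight list; loading
#' validates the shape manifest against the configuration.
#'
#' @param model a [LanguageModel-class].
#' @param path checkpoint path (.rds).
#' @return invisibly, the path; `loadModel` returns the model.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(config = list(
    nLayers = model@config@nLayers, dModel = model@config@dModel,
    nHeads = model@config@nHeads, contextLen = model@config@contextLen,
    vocabSize = model@config@vocabSize, initStd = model@config@initStd,
    seed = model@config@seed), params = model@params), path)
  invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
  obj <- readRDS(path)
  cfg <- do.call(modelConfig, obj$config)
  model <- new("LanguageModel", config = cfg, params = obj$params)
  ## shape manifest check
  ref <- initParams(cfg)
  ok <- TRUE
  chk <- function(nm, v) { ok <<- ok && !is.null(v); v }
  d <- dim(obj$params$wte)
  if (is.null(d) || d[1] != cfg@vocabSize || d[2] != cfg@dModel)
    stopf("checkpoint weight shapes do not match the stored configuration")
  model
}
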