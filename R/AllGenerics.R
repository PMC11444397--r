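#' Vocabulary size of a tokenizer or model
#' @param x a tokenizer or model object.
#' @return integer vocabulary size.
#' @export
setGeneric("vocabSize", function(x) standardGeneric("vocabSize"))

#' EOS token id
#' @param x a tokenizer or model object.
#' @return integer EOS id.
#' @export
setGeneric("eosId", function(x) standardGeneric("eosId"))

#' Next-token log-probability distribution
#'
#' Given a context of token ids (0-based), return the length-V vector of
#' natural-log probabilities for the next token. All decoding strategies are
#' written against this generic so they run identically on trained
#' transformers and on hand-specified toy models.
#'
#' @param model a [LanguageModel-class] or [TableModel-class].
#' @param ids integer vector of 0-based context token ids (non-empty).
#' @return numeric length-V vector of log-probabilities (logsumexp = 0).
#' @export
setGeneric("nextTokenLogProbs", function(model, ids) standardGeneric("nextTokenLogProbs"))

#' @export
setMethod("vocabSize", "BPETokenizer", function(x) length(x@vocab))
#' @export
setMethod("vocabSize", "LanguageModel", function(x) x@config@vocabSize)
#' @export
setMethod("vocabSize", "TableModel", function(x) x@vocabSize)
#' @export
setMethod("eosId", "BPETokenizer", function(x) x@eosId)
#' @export
setMethod("eosId", "LanguageModel", function(x) 0L)
#' @export
setMethod("eosId", "TableModel", function(x) x@eosId)

setMethod("show", "BPETokenizer", function(object) {
  cat("BPETokenizer with", length(object@vocab), "tokens (",
      nrow(object@merges), "merges ), EOS id", object@eosId, "\n")
  cat("  base symbols:", paste(object@baseSymbols, collapse = ""), "\n")
  if (!object@reachedTarget)
    cat("  note: training stopped before the requested vocabulary size\n")
})

setMethod("show", "ModelConfig", function(object) {
  cat(sprintf("ModelConfig: %d layers, d_model %d, %d heads, context %d, vocab %d\n",
              object@nLayers, object@dModel, object@nHeads,
              object@contextLen, object@vocabSize))
})

setMethod("show", "LanguageModel", function(object) {
  show(object@config)
  cat(sprintf("LanguageModel with %s trainable parameters\n",
              format(countParameters(object), big.mark = ",")))
})

setMethod("show", "KmerDistribution", function(object) {
  cat(sprintf("KmerDistribution: k = %d over %d k-mers, %s counted windows\n",
              object@k, length(object@counts), format(sum(object@counts))))
})

setMethod("show", "FoldResult", function(object) {
  cat(sprintf("FoldResult [%s]: score %.2f\n  %s\n",
              object@backend, object@score, object@structure))
})

setMethod("show", "GroupMFEResult", function(object) {
  cat("GroupMFEResult group means:\n")
  print(round(object@means, 3))
  print(object@tests)
})

setMethod("show", "AffinityModel", function(object) {
  cat(sprintf("AffinityModel: %d-nt PWM, logistic calibration (b0 %.3f, b1 %.3f)\n",
              object@motifWidth, object@coef[1], object@coef[2]))
  cat("  consensus:", pwmConsensus(object), "\n")
})

setMethod("show", "BindingDataset", function(object) {
  cat(sprintf("BindingDataset: %d positives, %d negatives\n",
              length(object@positives), length(object@negatives)))
  sizes <- vapply(object@partitions, length, integer(1))
  cat("  partitions:", paste(names(sizes), sizes, sep = "=", collapse = ", "), "\n")
})
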