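## Core S4 containers.

#' Byte-pair-encoding tokenizer for nucleotide sequences
#'
#' Holds an ordered merge list, the dense id/string vocabulary and the id of
#' the end-of-sequence (EOS) delimiter token. Token ids run 0..V-1 with no
#' gaps; id 0 is always EOS. Replaying `merges` over `baseSymbols` regenerates
#' the vocabulary exactly.
#'
#' @slot vocab character vector of token strings; position i holds id i-1.
#' @slot merges data.frame with columns `left`, `right`, `token` (strings), in
#'   merge-rank order.
#' @slot eosId integer id of the EOS token (always 0).
#' @slot baseSymbols the single-character symbols seen at training time.
#' @slot reachedTarget FALSE when training stopped before the requested
#'   vocabulary size because no pair occurred at least twice.
#' @export
setClass("BPETokenizer", representation(
  vocab = "character",
  merges = "data.frame",
  eosId = "integer",
  baseSymbols = "character",
  reachedTarget = "logical"
))

setValidity("BPETokenizer", function(object) {
  msg <- character()
  if (object@eosId != 0L) msg <- c(msg, "eosId must be 0")
  if (length(object@vocab) < 2L) msg <- c(msg, "vocabulary must contain EOS and at least one base symbol")
  if (anyDuplicated(object@vocab)) msg <- c(msg, "vocabulary strings must be unique")
  nonSpecial <- object@vocab[-(object@eosId + 1L)]
  if (any(nchar(nonSpecial) == 0L)) msg <- c(msg, "non-special tokens must be non-empty")
  if (length(msg)) msg else TRUE
})

#' Configuration of the causal decoder language model
#'
#' @slot nLayers number of transformer decoder layers.
#' @slot dModel model (embedding) dimension; must be divisible by `nHeads`.
#' @slot nHeads number of attention heads.
#' @slot contextLen maximum context window, in tokens.
#' @slot vocabSize vocabulary size V.
#' @slot initStd standard deviation of the Gaussian used for embedding and
#'   positional weights (default 0.02); linear layers use Kaiming (He)
#'   initialisation.
#' @slot seed integer seed for weight initialisation.
#' @export
setClass("ModelConfig", representation(
  nLayers = "integer", dModel = "integer", nHeads = "integer",
  contextLen = "integer", vocabSize = "integer",
  initStd = "numeric", seed = "integer"
))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (object@dModel %% object@nHeads != 0L)
    msg <- c(msg, "dModel must be divisible by nHeads")
  if (object@contextLen < 2L) msg <- c(msg, "contextLen must be >= 2")
  if (object@nLayers < 1L) msg <- c(msg, "nLayers must be >= 1")
  if (object@vocabSize < 2L) msg <- c(msg, "vocabSize must be >= 2")
  if (object@initStd <= 0) msg <- c(msg, "initStd must be positive")
  if (length(msg)) msg else TRUE
})

#' Causal decoder language model
#'
#' A GPT-2-lineage decoder-only transformer: learned token embedding (tied
#' with the output projection), learned absolute positional encoding, and
#' pre-normalisation blocks of causal self-attention plus a GELU feed-forward
#' network. `forwardLogProbs` emits one normalised next-token log-distribution
#' per input position; position t depends only on positions <= t.
#'
#' @slot config a [ModelConfig-class].
#' @slot params named list of weight matrices/vectors.
#' @export
setClass("LanguageModel", representation(config = "ModelConfig", params = "list"))

#' Hand-specified toy next-token model
#'
#' A tiny stand-in for [LanguageModel-class] whose next-token distribution is
#' looked up from an explicit table keyed by the context's token ids. Used to
#' exercise decoding algorithms against exhaustively enumerable models.
#'
#' @slot vocabSize vocabulary size.
#' @slot eosId EOS id (0).
#' @slot table named list: key = comma-joined context ids (possibly truncated
#'   to the last `order` ids), value = probability vector of length V.
#' @slot order context length used for lookup (0 = unconditional).
#' @slot default fallback distribution for unseen contexts.
#' @export
setClass("TableModel", representation(
  vocabSize = "integer", eosId = "integer", table = "list",
  order = "integer", default = "numeric"
))

#' k-mer count/frequency distribution
#'
#' Counts over all 4^k k-mers in lexicographic order (sliding window of 1 nt;
#' windows containing any ambiguity code are skipped).
#'
#' @slot k word length.
#' @slot counts named numeric vector of length 4^k.
#' @slot frequencies counts normalised to sum 1 (all-zero counts stay 0).
#' @export
setClass("KmerDistribution", representation(
  k = "integer", counts = "numeric", frequencies = "numeric"
))

setValidity("KmerDistribution", function(object) {
  if (length(object@counts) != 4^object@k) return("counts must have length 4^k")
  if (any(object@counts < 0)) return("counts must be non-negative")
  TRUE
})

#' Secondary-structure fold result
#'
#' @slot structure dot-bracket string, same length as the folded sequence.
#' @slot score energy-like score (lower = more stable; <= 0 for the built-in
#'   base-pair-weight backend).
#' @slot backend identifier of the folding backend used.
#' @export
setClass("FoldResult", representation(
  structure = "character", score = "numeric", backend = "character"
))

#' Result of the four-group MFE control experiment
#'
#' @slot scores named list of numeric score vectors for the generated,
#'   natural, shuffled and random groups.
#' @slot means named numeric vector of group means.
#' @slot tests data.frame of pairwise rank-sum comparisons (comparison,
#'   alternative, statistic, p.value).
#' @export
setClass("GroupMFEResult", representation(
  scores = "list", means = "numeric", tests = "data.frame"
))

#' PWM + logistic affinity scorer
#'
#' Stand-in for an external binding-affinity predictor: a position weight
#' matrix (log-odds vs background) scored over sliding windows, with a
#' logistic calibration mapping the best-window score into [0, 1].
#'
#' @slot pwm 4 x w log-odds matrix (rows A,C,G,T).
#' @slot background length-4 background base distribution.
#' @slot coef calibration intercept and slope of the logistic map.
#' @slot motifWidth motif width w.
#' @export
setClass("AffinityModel", representation(
  pwm = "matrix", background = "numeric", coef = "numeric", motifWidth = "integer"
))

#' Curated protein-binding dataset
#'
#' @slot positives deduplicated positive (binding) sequences.
#' @slot negatives deduplicated negative (background) sequences.
#' @slot partitions named list with elements `generator_finetune`,
#'   `scorer_train`, `test` (positives) and `neg_scorer_train`, `neg_test`
#'   (count-matched negatives).
#' @export
setClass("BindingDataset", representation(
  positives = "ANY", negatives = "ANY", partitions = "list"
))
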