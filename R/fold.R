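## Secondary-structure scoring. The built-in backend maximises weighted base
## pairs (G:C 3, A:T 2, G:T 1, minimum hairpin loop 3) by Nussinov-style
## O(n^3) dynamic programming with traceback; the score is reported negated
## (lower = more stable) in arbitrary energy-like units. Scores are
## comparable only within one backend. A pluggable backend contract lets a
## thermodynamic MFE engine take its place.

foldBackends <- new.env(parent = emptyenv())

#' Register a folding backend
#'
#' A backend is a function `function(sequence)` returning
#' `list(structure = <dot-bracket>, score = <numeric>)`.
#'
#' @param name backend identifier.
#' @param fn the backend function.
#' @return invisibly, the name.
#' @export
registerFoldBackend <- function(name, fn) {
  foldBackends[[name]] <- fn
  invisible(name)
}

#' Fold a sequence and return its structure score
#'
#' @param x a single sequence (ambiguity codes are forced unpaired by the
#'   built-in backend).
#' @param backend backend name (default "nussinov", the built-in base-pair
#'   weight maximiser).
#' @return a [FoldResult-class]; `score <= 0`, `structure` is balanced
#'   dot-bracket of the same length as the input.
#' @export
foldScore <- function(x, backend = "nussinov") {
  s <- as.character(x)
  if (length(s) != 1L) stopf("foldScore folds one sequence at a time; see foldScores()")
  if (!nzchar(s)) stopf("cannot fold an empty sequence")
  fn <- foldBackends[[backend]]
  if (is.null(fn)) stopf("unknown folding backend '%s'", backend)
  res <- fn(s)
  new("FoldResult", structure = res$structure, score = as.numeric(res$score),
      backend = backend)
}

#' Fold a set of sequences and return the score vector
#'
#' @param x sequences.
#' @param backend backend name.
#' @return named numeric vector of scores.
#' @export
foldScores <- function(x, backend = "nussinov") {
  d <- asDNA(x)
  vapply(seq_along(d), function(i)
    foldScore(as.character(d[[i]]), backend)@score, numeric(1)) |>
    setNames(names(d))
}

#' Write fold results in a two-line-per-record text format
#'
#' @param x sequences.
#' @param results list of [FoldResult-class] (folded on the fly if NULL).
#' @param path output path.
#' @param backend backend used when folding here.
#' @return invisibly, the path.
#' @export
writeFoldText <- function(x, path, results = NULL, backend = "nussinov") {
  d <- asDNA(x)
  if (is.null(results))
    results <- lapply(seq_along(d), function(i) foldScore(as.character(d[[i]]), backend))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(d)) {
    writeLines(sprintf(">%s score=%.2f", names(d)[i], results[[i]]@score), con)
    writeLines(sprintf("%s", as.character(d[[i]])), con)
    writeLines(results[[i]]@structure, con)
  }
  invisible(path)
}
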