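#' @import methods
#' @importFrom stats rnorm runif setNames glm binomial plogis wilcox.test pnorm dnorm
#' @importFrom utils head tail write.table read.table
#' @importFrom S4Vectors mcols mcols<- metadata metadata<-
#' @useDynLib rnalm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

IUPAC_NT <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
              "B", "D", "H", "V", "N")
BASES <- c("A", "C", "G", "T")

## Evaluate `expr` under a local RNG stream; the caller's RNG state is
## restored afterwards so no package function touches global randomness.
withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv()))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  expr
}

## Derive a child seed from a parent seed and a stream label, staying well
## below .Machine$integer.max so downstream set.seed() calls are valid.
deriveSeed <- function(seed, stream) {
  if (is.null(seed)) return(NULL)
  h <- as.numeric(seed) %% 2147483629
  for (code in utf8ToInt(as.character(stream)))
    h <- (h * 131 + code) %% 2147483629
  as.integer(h)
}

## Coerce character vectors / DNAStringSet to a named DNAStringSet.
asDNA <- function(x, ids = NULL) {
  if (is(x, "DNAStringSet")) {
    if (!is.null(ids)) names(x) <- ids
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(x)
  }
  nm <- names(x)
  x <- as.character(x)
  if (is.null(ids))
    ids <- if (is.null(nm)) paste0("seq", seq_along(x)) else nm
  out <- Biostrings::DNAStringSet(unname(x))
  if (length(out)) names(out) <- ids
  out
}

seqChars <- function(x) strsplit(as.character(x), "", fixed = TRUE)

#' Render a DNA sequence set as RNA (T to U)
#'
#' The package works on the DNA alphabet internally; this converts T to U for
#' output, mirroring the U-to-T normalisation applied on input.
#'
#' @param x a `DNAStringSet` or character vector.
#' @return a character vector over the RNA alphabet.
#' @export
asRNAOutput <- function(x) {
  chartr("T", "U", as.character(x))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
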