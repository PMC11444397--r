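## Independent oracles used to check the package implementations. These are
## deliberately naive and share no code with the implementation paths.

## Exhaustive recursive maximiser of weighted base pairs (G:C 3, A:T 2,
## G:T 1, min loop 3). No memoisation beyond recursion; feasible for n <= 12.
bruteFoldWeight <- function(s) {
  ch <- strsplit(s, "")[[1]]
  w <- function(a, b) {
    key <- paste0(a, b)
    switch(key, GC = 3, CG = 3, AT = 2, TA = 2, GT = 1, TG = 1, 0)
  }
  rec <- function(i, j) {
    if (j - i < 4) return(0)
    best <- rec(i + 1, j)                       # i unpaired
    for (t in (i + 4):j) {
      wt <- w(ch[i], ch[t])
      if (wt > 0) {
        inner <- if (t - 1 >= i + 1) rec(i + 1, t - 1) else 0
        rest <- if (t + 1 <= j) rec(t + 1, j) else 0
        best <- max(best, wt + inner + rest)
      }
    }
    best
  }
  n <- length(ch)
  if (n < 2) return(0)
  rec(1, n)
}

## Full Smith-Waterman with affine gaps (match +1, mismatch -1, first gap
## residue -3 = opening 2 + extension 1, further residues -1), pure R Gotoh.
swOracleScore <- function(a, b) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      sub <- if (A[i - 1] == B[j - 1]) 1 else -1
      M[i, j] <- max(0, max(M[i - 1, j - 1], Ix[i - 1, j - 1], Iy[i - 1, j - 1]) + sub)
      Ix[i, j] <- max(M[i - 1, j] - 3, Ix[i - 1, j] - 1)
      Iy[i, j] <- max(M[i, j - 1] - 3, Iy[i, j - 1] - 1)
      best <- max(best, M[i, j])
    }
  }
  best
}

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste0(sample(alphabet, n, replace = TRUE), collapse = "")
}

kmerCountVector <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(table(character(0)))
  table(substring(s, seq_len(n - k + 1), seq(k, n)))
}
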