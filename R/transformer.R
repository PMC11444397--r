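## Internal numerics of the causal decoder model. Everything here works on a
## flat parameter list and plain matrices; the user-facing S4 wrappers live in
## lm-api.R. Batches of B sequences of equal length L are held as a
## (B*L) x d activation matrix, rows sample-major, so the linear algebra runs
## through BLAS; only the per-sample attention matrices are looped.

LN_EPS <- 1e-5

rowMaxs <- function(m) m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]

logSoftmaxRows <- function(logits) {
  mx <- rowMaxs(logits)
  z <- logits - mx
  z - log(rowSums(exp(z)))
}

softmaxRows <- function(logits) {
  mx <- rowMaxs(logits)
  e <- exp(logits - mx)
  e / rowSums(e)
}

geluFwd <- function(a) a * pnorm(a)
geluGrad <- function(a) pnorm(a) + a * dnorm(a)

bcastRow <- function(v, n) matrix(v, n, length(v), byrow = TRUE)

lnForward <- function(x, g, b) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + LN_EPS)
  xhat <- xc * inv
  list(y = xhat * bcastRow(g, nrow(x)) + bcastRow(b, nrow(x)),
       xhat = xhat, inv = inv)
}

lnBackward <- function(dy, cache, g) {
  xhat <- cache$xhat
  dg <- colSums(dy * xhat)
  db <- colSums(dy)
  dxhat <- dy * bcastRow(g, nrow(dy))
  dx <- (dxhat - rowMeans(dxhat) - xhat * rowMeans(dxhat * xhat)) * cache$inv
  list(dx = dx, dg = dg, db = db)
}

initLayerParams <- function(d, dff) {
  kaiming <- function(nin, nout) matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
  list(
    ln1g = rep(1, d), ln1b = rep(0, d),
    wq = kaiming(d, d), bq = rep(0, d),
    wk = kaiming(d, d), bk = rep(0, d),
    wv = kaiming(d, d), bv = rep(0, d),
    wo = kaiming(d, d), bo = rep(0, d),
    ln2g = rep(1, d), ln2b = rep(0, d),
    w1 = kaiming(d, dff), b1 = rep(0, dff),
    w2 = kaiming(dff, d), b2 = rep(0, d))
}

initParams <- function(cfg) {
  d <- cfg@dModel
  withSeed(cfg@seed, {
    params <- list(
      wte = matrix(rnorm(cfg@vocabSize * d, 0, cfg@initStd), cfg@vocabSize, d),
      wpe = matrix(rnorm(cfg@contextLen * d, 0, cfg@initStd), cfg@contextLen, d),
      layers = lapply(seq_len(cfg@nLayers), function(i) initLayerParams(d, 4L * d)),
      lnfg = rep(1, d), lnfb = rep(0, d))
    params
  })
}

## Forward pass over a batch. idsMat: B x L matrix of 0-based ids.
## Returns logits and, when keepCache, everything backward needs.
lmForwardCore <- function(params, cfg, idsMat, keepCache = FALSE) {
  B <- nrow(idsMat); L <- ncol(idsMat)
  d <- cfg@dModel; H <- cfg@nHeads; dh <- d %/% H
  if (L > cfg@contextLen) stopf("input length %d exceeds context %d", L, cfg@contextLen)
  if (any(idsMat < 0 | idsMat >= cfg@vocabSize)) stopf("token id out of range")
  idsFlat <- as.integer(t(idsMat))                 # sample-major row order
  posFlat <- rep(seq_len(L), B)
  X <- params$wte[idsFlat + 1L, , drop = FALSE] + params$wpe[posFlat, , drop = FALSE]
  mask <- outer(seq_len(L), seq_len(L), ">=")      # TRUE where key <= query
  rowsOf <- function(b) ((b - 1L) * L + 1L):(b * L)
  colsOf <- function(h) ((h - 1L) * dh + 1L):(h * dh)
  cache <- if (keepCache) list(idsFlat = idsFlat, posFlat = posFlat, layers = vector("list", cfg@nLayers))
  for (li in seq_len(cfg@nLayers)) {
    lp <- params$layers[[li]]
    ln1 <- lnForward(X, lp$ln1g, lp$ln1b)
    h <- ln1$y
    Q <- h %*% lp$wq + bcastRow(lp$bq, B * L)
    K <- h %*% lp$wk + bcastRow(lp$bk, B * L)
    V <- h %*% lp$wv + bcastRow(lp$bv, B * L)
    O <- matrix(0, B * L, d)
    A <- if (keepCache) vector("list", B * H)
    for (b in seq_len(B)) {
      rws <- rowsOf(b)
      for (hd in seq_len(H)) {
        cls <- colsOf(hd)
        S <- (Q[rws, cls, drop = FALSE] %*% t(K[rws, cls, drop = FALSE])) / sqrt(dh)
        S[!mask] <- -1e30
        Abh <- softmaxRows(S)
        O[rws, cls] <- Abh %*% V[rws, cls, drop = FALSE]
        if (keepCache) A[[(b - 1L) * H + hd]] <- Abh
      }
    }
    attnOut <- O %*% lp$wo + bcastRow(lp$bo, B * L)
    X1 <- X + attnOut
    ln2 <- lnForward(X1, lp$ln2g, lp$ln2b)
    a <- ln2$y %*% lp$w1 + bcastRow(lp$b1, B * L)
    gact <- geluFwd(a)
    X2 <- X1 + gact %*% lp$w2 + bcastRow(lp$b2, B * L)
    if (keepCache)
      cache$layers[[li]] <- list(ln1 = ln1, h = h, Q = Q, K = K, V = V, O = O,
                                 A = A, X = X, X1 = X1, ln2 = ln2, a = a, gact = gact)
    X <- X2
  }
  lnf <- lnForward(X, params$lnfg, params$lnfb)
  logits <- lnf$y %*% t(params$wte)
  if (keepCache) { cache$lnf <- lnf; cache$Xfinal <- X; cache$B <- B; cache$L <- L }
  list(logits = logits, cache = cache)
}

## Cross-entropy loss and full gradient. targetMat: B x L of 0-based target
## ids with NA at excluded (padding) positions. Loss is the mean NLL per
## counted target token, in nats.
lmLossGrad <- function(params, cfg, idsMat, targetMat) {
  fw <- lmForwardCore(params, cfg, idsMat, keepCache = TRUE)
  cache <- fw$cache
  B <- cache$B; L <- cache$L
  d <- cfg@dModel; H <- cfg@nHeads; dh <- d %/% H
  tFlat <- as.integer(t(targetMat))
  sel <- which(!is.na(tFlat))
  nT <- length(sel)
  if (nT == 0L) stopf("no target tokens in batch")
  logp <- logSoftmaxRows(fw$logits[sel, , drop = FALSE])
  loss <- -mean(logp[cbind(seq_len(nT), tFlat[sel] + 1L)])
  if (!is.finite(loss)) return(list(loss = loss, grads = NULL))

  grads <- list(wte = matrix(0, cfg@vocabSize, d),
                wpe = matrix(0, cfg@contextLen, d),
                layers = vector("list", cfg@nLayers),
                lnfg = NULL, lnfb = NULL)
  dlogits <- matrix(0, B * L, cfg@vocabSize)
  P <- exp(logp)
  P[cbind(seq_len(nT), tFlat[sel] + 1L)] <- P[cbind(seq_len(nT), tFlat[sel] + 1L)] - 1
  dlogits[sel, ] <- P / nT
  ## output projection is the tied embedding
  grads$wte <- grads$wte + t(dlogits) %*% cache$lnf$y
  dXf <- dlogits %*% params$wte
  lnfB <- lnBackward(dXf, cache$lnf, params$lnfg)
  grads$lnfg <- lnfB$dg; grads$lnfb <- lnfB$db
  dX <- lnfB$dx

  mask <- outer(seq_len(L), seq_len(L), ">=")
  rowsOf <- function(b) ((b - 1L) * L + 1L):(b * L)
  colsOf <- function(h) ((h - 1L) * dh + 1L):(h * dh)
  for (li in rev(seq_len(cfg@nLayers))) {
    lp <- params$layers[[li]]
    lc <- cache$layers[[li]]
    g <- list()
    ## MLP branch
    dOut <- dX                                  # gradient of X2 w.r.t. both summands
    dgact <- dOut %*% t(lp$w2)
    g$w2 <- t(lc$gact) %*% dOut
    g$b2 <- colSums(dOut)
    da <- dgact * geluGrad(lc$a)
    g$w1 <- t(lc$ln2$y) %*% da
    g$b1 <- colSums(da)
    dh2 <- da %*% t(lp$w1)
    ln2B <- lnBackward(dh2, lc$ln2, lp$ln2g)
    g$ln2g <- ln2B$dg; g$ln2b <- ln2B$db
    dX1 <- dX + ln2B$dx
    ## attention branch
    dAttnOut <- dX1
    g$wo <- t(lc$O) %*% dAttnOut
    g$bo <- colSums(dAttnOut)
    dO <- dAttnOut %*% t(lp$wo)
    dQ <- matrix(0, nrow(dO), d); dK <- matrix(0, nrow(dO), d); dV <- matrix(0, nrow(dO), d)
    B_ <- cache$B
    for (b in seq_len(B_)) {
      rws <- rowsOf(b)
      for (hd in seq_len(cfg@nHeads)) {
        cls <- colsOf(hd)
        A <- lc$A[[(b - 1L) * cfg@nHeads + hd]]
        dObh <- dO[rws, cls, drop = FALSE]
        Vbh <- lc$V[rws, cls, drop = FALSE]
        dA <- dObh %*% t(Vbh)
        dV[rws, cls] <- t(A) %*% dObh
        dS <- A * (dA - rowSums(dA * A))
        dS <- dS / sqrt(dh)
        dS[!mask] <- 0
        dQ[rws, cls] <- dS %*% lc$K[rws, cls, drop = FALSE]
        dK[rws, cls] <- t(dS) %*% lc$Q[rws, cls, drop = FALSE]
      }
    }
    hmat <- lc$h
    g$wq <- t(hmat) %*% dQ; g$bq <- colSums(dQ)
    g$wk <- t(hmat) %*% dK; g$bk <- colSums(dK)
    g$wv <- t(hmat) %*% dV; g$bv <- colSums(dV)
    dhTot <- dQ %*% t(lp$wq) + dK %*% t(lp$wk) + dV %*% t(lp$wv)
    ln1B <- lnBackward(dhTot, lc$ln1, lp$ln1g)
    g$ln1g <- ln1B$dg; g$ln1b <- ln1B$db
    dX <- dX1 + ln1B$dx
    grads$layers[[li]] <- g
  }
  ## embedding + positional gradients (gather-scatter)
  emb <- rowsum(dX, group = cache$idsFlat)
  grads$wte[as.integer(rownames(emb)) + 1L, ] <-
    grads$wte[as.integer(rownames(emb)) + 1L, , drop = FALSE] + emb
  pos <- rowsum(dX, group = cache$posFlat)
  grads$wpe[as.integer(rownames(pos)), ] <- pos
  list(loss = loss, grads = grads)
}

## Flatten/iterate parameter lists for the optimizer.
paramWalk <- function(params, fn) {
  params$wte <- fn("wte", params$wte)
  params$wpe <- fn("wpe", params$wpe)
  for (li in seq_along(params$layers))
    for (nm in names(params$layers[[li]]))
      params$layers[[li]][[nm]] <- fn(paste0("L", li, ".", nm), params$layers[[li]][[nm]])
  params$lnfg <- fn("lnfg", params$lnfg)
  params$lnfb <- fn("lnfb", params$lnfb)
  params
}

gradGlobalNorm <- function(grads) {
  tot <- 0
  collect <- function(nm, v) { tot <<- tot + sum(v * v); v }
  invisible(paramWalk(grads, collect))
  sqrt(tot)
}
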