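## Internal neural layers: forward passes return a list(out, cache); backward
## passes take the upstream gradient plus the cache and return input gradients
## and a parameter-gradient tree shaped like the parameter tree.
## All matrices are row-major in the sequence dimension (rows = time steps or
## latents, columns = features).

## ---- dropout ---------------------------------------------------------------

dropoutFwd <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL))
  mask <- (matrix(runif(length(x)), nrow(x), ncol(x)) >= rate) / (1 - rate)
  list(out = x * mask, mask = mask)
}

dropoutBwd <- function(dy, cache) {
  if (is.null(cache$mask)) dy else dy * cache$mask
}

## ---- layer normalisation (per row, over features) -------------------------

lnInit <- function(w) list(g = rep(1, w), b = rep(0, w))

lnFwd <- function(x, p, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc^2)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- addBias(xhat * rep(p$g, each = nrow(x)), p$b)
  list(out = out, xhat = xhat, inv = inv)
}

lnBwd <- function(dy, cache, p) {
  n <- nrow(dy)
  dg <- colSums(dy * cache$xhat)
  db <- colSums(dy)
  dxhat <- dy * rep(p$g, each = n)
  dx <- cache$inv *
    (dxhat - rowMeans(dxhat) - cache$xhat * rowMeans(dxhat * cache$xhat))
  list(dx = dx, grads = list(g = dg, b = db))
}

## ---- scaled dot-product attention (multi-head) ----------------------------

attnInit <- function(wq, wkv, dk) {
  list(Wq = initMat(wq, dk, 1 / sqrt(wq)),
       Wk = initMat(wkv, dk, 1 / sqrt(wkv)),
       Wv = initMat(wkv, dk, 1 / sqrt(wkv)),
       Wo = initMat(dk, wq, 1 / sqrt(dk)),
       bo = rep(0, wq))
}

attnFwd <- function(xq, xkv, p, nHeads = 1L) {
  dk <- ncol(p$Wq)
  dh <- dk %/% nHeads
  Q <- xq %*% p$Wq
  K <- xkv %*% p$Wk
  V <- xkv %*% p$Wv
  O <- matrix(0, nrow(Q), dk)
  A <- vector("list", nHeads)
  for (h in seq_len(nHeads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    S <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    A[[h]] <- softmaxRows(S)
    O[, cols] <- A[[h]] %*% V[, cols, drop = FALSE]
  }
  out <- addBias(O %*% p$Wo, p$bo)
  list(out = out, xq = xq, xkv = xkv, Q = Q, K = K, V = V, A = A, O = O)
}

attnBwd <- function(dout, cache, p, nHeads = 1L) {
  dk <- ncol(p$Wq)
  dh <- dk %/% nHeads
  dWo <- crossprod(cache$O, dout)
  dbo <- colSums(dout)
  dO <- dout %*% t(p$Wo)
  dQ <- matrix(0, nrow(cache$Q), dk)
  dK <- matrix(0, nrow(cache$K), dk)
  dV <- matrix(0, nrow(cache$V), dk)
  for (h in seq_len(nHeads)) {
    cols <- ((h - 1L) * dh + 1L):(h * dh)
    Ah <- cache$A[[h]]
    dOh <- dO[, cols, drop = FALSE]
    Vh <- cache$V[, cols, drop = FALSE]
    dA <- dOh %*% t(Vh)
    dV[, cols] <- crossprod(Ah, dOh)
    dS <- Ah * (dA - rowSums(dA * Ah))
    dS <- dS / sqrt(dh)
    dQ[, cols] <- dS %*% cache$K[, cols, drop = FALSE]
    dK[, cols] <- crossprod(dS, cache$Q[, cols, drop = FALSE])
  }
  list(dxq = dQ %*% t(p$Wq),
       dxkv = dK %*% t(p$Wk) + dV %*% t(p$Wv),
       grads = list(Wq = crossprod(cache$xq, dQ),
                    Wk = crossprod(cache$xkv, dK),
                    Wv = crossprod(cache$xkv, dV),
                    Wo = dWo, bo = dbo))
}

## ---- transformer block (attention + residual + LN + feed-forward) ---------
## Post-norm layout, identical for self- and cross-attention so that the
## Perceiver/transformer FLOP comparison compares like with like.

blockInit <- function(wq, wkv, dk, ffMult = 4L) {
  ff <- ffMult * wq
  list(attn = attnInit(wq, wkv, dk),
       ln1 = lnInit(wq),
       W1 = initMat(wq, ff, 1 / sqrt(wq)), b1 = rep(0, ff),
       W2 = initMat(ff, wq, 1 / sqrt(ff)), b2 = rep(0, wq),
       ln2 = lnInit(wq))
}

blockFwd <- function(xq, xkv, p, nHeads = 1L, dropout = 0, train = FALSE) {
  a <- attnFwd(xq, xkv, p$attn, nHeads)
  d1 <- dropoutFwd(a$out, dropout, train)
  r1 <- xq + d1$out
  n1 <- lnFwd(r1, p$ln1)
  h <- addBias(n1$out %*% p$W1, p$b1)
  hr <- pmax(h, 0)
  f <- addBias(hr %*% p$W2, p$b2)
  d2 <- dropoutFwd(f, dropout, train)
  r2 <- n1$out + d2$out
  n2 <- lnFwd(r2, p$ln2)
  list(out = n2$out,
       a = a, d1 = d1, n1 = n1, h = h, hr = hr, d2 = d2, n2 = n2)
}

blockBwd <- function(dout, cache, p, nHeads = 1L) {
  l2 <- lnBwd(dout, cache$n2, p$ln2)
  dr2 <- l2$dx
  df <- dropoutBwd(dr2, cache$d2)
  dW2 <- crossprod(cache$hr, df)
  db2 <- colSums(df)
  dhr <- df %*% t(p$W2)
  dh <- dhr * (cache$h > 0)
  dW1 <- crossprod(cache$n1$out, dh)
  db1 <- colSums(dh)
  dn1 <- dr2 + dh %*% t(p$W1)
  l1 <- lnBwd(dn1, cache$n1, p$ln1)
  dr1 <- l1$dx
  da <- dropoutBwd(dr1, cache$d1)
  ab <- attnBwd(da, cache$a, p$attn, nHeads)
  list(dxq = dr1 + ab$dxq,
       dxkv = ab$dxkv,
       grads = list(attn = ab$grads, ln1 = l1$grads,
                    W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    ln2 = l2$grads))
}

## ---- single-hidden-layer embedding MLP (row-wise) --------------------------

embedInit <- function(D, e, hidden = 32L) {
  list(W1 = initMat(D, hidden, 1 / sqrt(D)), b1 = rep(0, hidden),
       W2 = initMat(hidden, e, 1 / sqrt(hidden)), b2 = rep(0, e))
}

embedFwd <- function(x, p) {
  h <- addBias(x %*% p$W1, p$b1)
  hr <- pmax(h, 0)
  list(out = addBias(hr %*% p$W2, p$b2), x = x, h = h, hr = hr)
}

embedBwd <- function(dy, cache, p) {
  dW2 <- crossprod(cache$hr, dy)
  db2 <- colSums(dy)
  dhr <- dy %*% t(p$W2)
  dh <- dhr * (cache$h > 0)
  list(dx = dh %*% t(p$W1),
       grads = list(W1 = crossprod(cache$x, dh), b1 = colSums(dh),
                    W2 = dW2, b2 = db2))
}

## ---- classifier head: mean-pool rows, affine, logistic --------------------

headInit <- function(w) list(w = rnorm(w, sd = 1 / sqrt(w)), b = 0)

headFwd <- function(H, p) {
  pooled <- colMeans(H)
  z <- sum(pooled * p$w) + p$b
  list(prob = sigmoid(z), pooled = pooled, z = z, nrowH = nrow(H))
}

## dz is the gradient at the logit (pre-sigmoid).
headBwd <- function(dz, cache, p) {
  dpooled <- dz * p$w
  dH <- matrix(rep(dpooled / cache$nrowH, each = cache$nrowH),
               cache$nrowH, length(p$w))
  list(dH = dH, grads = list(w = dz * cache$pooled, b = dz))
}
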