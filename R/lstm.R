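## Two-layer unidirectional LSTM (hidden size 50 by default) consuming
## carry-forward-filled regular series; the classifier reads the final
## hidden state of the top layer. Gate column order within the 4H-wide
## projections: input, forget, cell, output.

lstmLayerInit <- function(din, H) {
  list(W = initMat(din, 4L * H, 1 / sqrt(din)),
       U = initMat(H, 4L * H, 1 / sqrt(H)),
       b = rep(0, 4L * H))
}

lstmInit <- function(D, H = 50L) {
  list(l1 = lstmLayerInit(D, H),
       l2 = lstmLayerInit(H, H),
       head = headInit(H))
}

## X: B x T x D array. Returns per-patient probabilities plus caches.
lstmFwd <- function(X, params, H, dropout = 0, train = FALSE) {
  B <- dim(X)[1L]; T <- dim(X)[2L]
  layers <- list(params$l1, params$l2)
  caches <- list()
  inp <- lapply(seq_len(T), function(t) matrix(X[, t, ], B))
  for (li in 1:2) {
    p <- layers[[li]]
    h <- matrix(0, B, H); cst <- matrix(0, B, H)
    steps <- vector("list", T)
    outs <- vector("list", T)
    for (t in seq_len(T)) {
      A <- addBias(inp[[t]] %*% p$W + h %*% p$U, p$b)
      i <- sigmoid(A[, 1:H, drop = FALSE])
      f <- sigmoid(A[, (H + 1):(2 * H), drop = FALSE])
      g <- tanh(A[, (2 * H + 1):(3 * H), drop = FALSE])
      o <- sigmoid(A[, (3 * H + 1):(4 * H), drop = FALSE])
      cNew <- f * cst + i * g
      tc <- tanh(cNew)
      hNew <- o * tc
      steps[[t]] <- list(x = inp[[t]], hPrev = h, cPrev = cst,
                         i = i, f = f, g = g, o = o, tc = tc)
      h <- hNew; cst <- cNew
      outs[[t]] <- hNew
    }
    drop <- NULL
    if (li == 1L) {
      drop <- lapply(outs, function(hh) dropoutFwd(hh, dropout, train))
      inp <- lapply(drop, `[[`, "out")
    }
    caches[[li]] <- list(steps = steps, drop = drop)
  }
  ## classifier reads the final top-layer hidden state, one logit per patient
  z <- as.vector(h %*% params$head$w) + params$head$b
  list(probs = sigmoid(z), z = z, hTop = h, caches = caches)
}

## dz: per-patient gradient at the logit (length B).
lstmBwd <- function(dz, fwd, params, H) {
  B <- length(dz)
  grads <- treeZero(params)
  grads$head$w <- as.vector(crossprod(fwd$hTop, dz))
  grads$head$b <- sum(dz)
  dhTop <- outer(dz, params$head$w)
  layers <- list(params$l1, params$l2)
  dInp <- NULL # per-time-step input grads from the layer above
  for (li in 2:1) {
    p <- layers[[li]]
    cc <- fwd$caches[[li]]
    T <- length(cc$steps)
    dh <- if (li == 2L) dhTop else matrix(0, B, H)
    dc <- matrix(0, B, H)
    dW <- grads[[li]]$W; dU <- grads[[li]]$U; db <- grads[[li]]$b
    dx <- vector("list", T)
    for (t in rev(seq_len(T))) {
      st <- cc$steps[[t]]
      if (li == 1L && !is.null(dInp))
        dh <- dh + dropoutBwd(dInp[[t]], fwd$caches[[1L]]$drop[[t]])
      dco <- dc + dh * st$o * (1 - st$tc^2)
      dA <- cbind(dco * st$g * st$i * (1 - st$i),
                  dco * st$cPrev * st$f * (1 - st$f),
                  dco * st$i * (1 - st$g^2),
                  dh * st$tc * st$o * (1 - st$o))
      dW <- dW + crossprod(st$x, dA)
      dU <- dU + crossprod(st$hPrev, dA)
      db <- db + colSums(dA)
      dx[[t]] <- dA %*% t(p$W)
      dh <- dA %*% t(p$U)
      dc <- dco * st$f
    }
    grads[[li]]$W <- dW; grads[[li]]$U <- dU; grads[[li]]$b <- db
    dInp <- dx
  }
  grads
}
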