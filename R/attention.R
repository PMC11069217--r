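#' Attention encoder configuration
#'
#' Defaults follow the study configuration: key/query width `dModel = 128`
#' shared by cross- and self-attention, a single head, one cross-attention
#' (`M = 1`) and one self-attention (`N = 1`) layer, dropout 0.5, and the
#' number of latents `l` equal to the number of time steps. The latent
#' feature width `latentDim` defaults to the input embedding width `e`; it
#' may be set independently (e.g. 64 with `e = 32`), in which case queries
#' and all post-cross-attention processing live in `latentDim` dimensions
#' while keys/values come from the `e`-dimensional input.
#'
#' @param e input embedding width (d_model of the sequence).
#' @param dk key/query projection width (default 128).
#' @param nHeads number of attention heads; must divide `dk`.
#' @param M number of cross-attention operations, averaged (default 1).
#' @param N number of self-attention layers (default 1; 0 allowed).
#' @param l number of latents (default `NULL` = number of time steps).
#' @param latentDim latent feature width (default `e`).
#' @param dropout dropout rate in attention blocks (default 0.5).
#' @param ffMult feed-forward expansion factor (default 4).
#' @return A list of class `"attentionConfig"`.
#' @export
attentionConfig <- function(e = 32L, dk = 128L, nHeads = 1L, M = 1L, N = 1L,
                            l = NULL, latentDim = e, dropout = 0.5,
                            ffMult = 4L) {
  stopifnot(M >= 1L, N >= 0L, nHeads >= 1L)
  if (dk %% nHeads != 0L) stop("dk must be divisible by nHeads")
  if (!is.null(l) && l < 1L) stop("need at least one latent")
  if (dropout < 0 || dropout >= 1) stop("dropout must be in [0, 1)")
  structure(list(e = as.integer(e), dk = as.integer(dk),
                 nHeads = as.integer(nHeads), M = as.integer(M),
                 N = as.integer(N), l = if (is.null(l)) NULL else as.integer(l),
                 latentDim = as.integer(latentDim), dropout = dropout,
                 ffMult = as.integer(ffMult)),
            class = "attentionConfig")
}

#' Scaled dot-product attention
#'
#' `softmax(Q K^T / sqrt(d_k)) V`, the attention primitive shared by the
#' self- and cross-attention operations. Returned weights are the softmax
#' matrix, for inspection and testing.
#'
#' @param Q queries, `q x d_k`.
#' @param K keys, `k x d_k`.
#' @param V values, `k x d_v`.
#' @return list with `output` (`q x d_v`) and `weights` (`q x k`, rows
#'   summing to 1).
#' @export
scaledDotProductAttention <- function(Q, K, V) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stop("Q and K must share column count d_k")
  if (nrow(K) != nrow(V)) stop("K and V must share row count")
  W <- softmaxRows(Q %*% t(K) / sqrt(ncol(K)))
  list(output = W %*% V, weights = W)
}

#' Sinusoidal positional encoding
#'
#' `PE[pos, 2i] = sin(pos / 10000^(2i/d_model))` and
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/d_model))`, for positions
#' `0..T-1`. Added elementwise to the input sequence before attention so the
#' order of time steps is retained.
#'
#' @param T sequence length.
#' @param dModel encoding width; must be even (paired sin/cos columns).
#' @return `T x dModel` matrix with entries in `[-1, 1]`.
#' @export
positionalEncoding <- function(T, dModel) {
  if (dModel %% 2L != 0L) stop("dModel must be even (paired sin/cos columns)")
  pos <- 0:(T - 1L)
  pe <- matrix(0, T, dModel)
  for (i in seq_len(dModel / 2L)) {
    twoI <- 2L * (i - 1L)
    div <- 10000^(twoI / dModel)
    pe[, twoI + 1L] <- sin(pos / div)
    pe[, twoI + 2L] <- cos(pos / div)
  }
  pe
}

#' Seeded learnable latent bank
#'
#' The `l x latentDim` array of latents that cross-attention squeezes the
#' input sequence into; initialised as Gaussian noise (sd 0.02) and trained
#' with the rest of the model.
#'
#' @param l number of latents.
#' @param latentDim latent feature width.
#' @param seed integer seed.
#' @export
latentBank <- function(l, latentDim, seed = 1L) {
  withSeed(deriveSeed(seed, "latents"), initMat(l, latentDim, 0.02))
}

## ---- encoder parameter trees ----------------------------------------------
## Perceiver: latents Z (l x L), M cross blocks (queries width L, keys/values
## width e), N self blocks (width L). Transformer: M + N self blocks on width
## e (same pipeline with cross-attention replaced by self-attention; no
## latents). Initialisation consumes the current RNG stream.

initPerceiverParams <- function(cfg, T) {
  l <- if (is.null(cfg$l)) T else cfg$l
  L <- cfg$latentDim
  list(Z = initMat(l, L, 0.02),
       cross = lapply(seq_len(cfg$M), function(m)
         blockInit(L, cfg$e, cfg$dk, cfg$ffMult)),
       selfb = lapply(seq_len(cfg$N), function(nn)
         blockInit(L, L, cfg$dk, cfg$ffMult)))
}

initTransformerParams <- function(cfg, T) {
  list(cross = lapply(seq_len(cfg$M), function(m)
         blockInit(cfg$e, cfg$e, cfg$dk, cfg$ffMult)),
       selfb = lapply(seq_len(cfg$N), function(nn)
         blockInit(cfg$e, cfg$e, cfg$dk, cfg$ffMult)))
}

## Shared encoder forward. `kind` is "perceiver" (queries = latents) or
## "transformer" (queries = the input itself). Positional encoding is added
## to the input here.
encoderFwd <- function(X, params, cfg, kind, train = FALSE) {
  pe <- positionalEncoding(nrow(X), ncol(X))
  Xp <- X + pe
  xq0 <- if (kind == "perceiver") params$Z else Xp
  stage1 <- lapply(params$cross, function(p)
    blockFwd(xq0, Xp, p, cfg$nHeads, cfg$dropout, train))
  H <- Reduce(`+`, lapply(stage1, `[[`, "out")) / length(stage1)
  selfCaches <- vector("list", cfg$N)
  for (i in seq_len(cfg$N)) {
    selfCaches[[i]] <- blockFwd(H, H, params$selfb[[i]],
                                cfg$nHeads, cfg$dropout, train)
    H <- selfCaches[[i]]$out
  }
  list(out = H, stage1 = stage1, selfCaches = selfCaches, kind = kind)
}

encoderBwd <- function(dH, cache, params, cfg) {
  for (i in rev(seq_len(cfg$N))) {
    bb <- blockBwd(dH, cache$selfCaches[[i]], params$selfb[[i]], cfg$nHeads)
    selfGrad <- bb$grads
    if (i == cfg$N) selfGrads <- vector("list", cfg$N)
    selfGrads[[i]] <- selfGrad
    dH <- bb$dxq + bb$dxkv
  }
  if (cfg$N == 0L) selfGrads <- list()
  M <- length(params$cross)
  dXp <- NULL
  dZ <- NULL
  crossGrads <- vector("list", M)
  for (m in seq_len(M)) {
    bb <- blockBwd(dH / M, cache$stage1[[m]], params$cross[[m]], cfg$nHeads)
    crossGrads[[m]] <- bb$grads
    if (cache$kind == "perceiver") {
      dZ <- if (is.null(dZ)) bb$dxq else dZ + bb$dxq
      dXp <- if (is.null(dXp)) bb$dxkv else dXp + bb$dxkv
    } else {
      dXp <- if (is.null(dXp)) bb$dxq + bb$dxkv else dXp + bb$dxq + bb$dxkv
    }
  }
  grads <- list(cross = crossGrads, selfb = selfGrads)
  if (cache$kind == "perceiver") grads <- c(list(Z = dZ), grads)
  list(dX = dXp, grads = grads)
}

#' Cross-attention block: squeeze a sequence into latents
#'
#' One transformer block whose queries are projected from the latent bank and
#' whose keys/values come from the input sequence; applied `M` times with
#' separate parameters and averaged elementwise.
#'
#' @param X input sequence, `T x e` (positional encoding NOT added here).
#' @param latents `l x latentDim` latent bank, e.g. from [latentBank()].
#' @param cfg an [attentionConfig()].
#' @param params optional parameter tree (list of `M` block parameter sets);
#'   initialised from `seed` when omitted.
#' @param seed seed for parameter initialisation.
#' @param train logical; enables dropout.
#' @return `l x latentDim` matrix.
#' @export
crossAttentionBlock <- function(X, latents, cfg = attentionConfig(e = ncol(X)),
                                params = NULL, seed = 1L, train = FALSE) {
  if (ncol(X) != cfg$e) stop("input width must equal cfg$e")
  if (ncol(latents) != cfg$latentDim)
    stop("latent width must equal cfg$latentDim")
  if (is.null(params))
    params <- withSeed(deriveSeed(seed, "cross"),
                       lapply(seq_len(cfg$M), function(m)
                         blockInit(cfg$latentDim, cfg$e, cfg$dk, cfg$ffMult)))
  outs <- lapply(params, function(p)
    blockFwd(latents, X, p, cfg$nHeads, cfg$dropout, train)$out)
  Reduce(`+`, outs) / length(outs)
}

#' Self-attention block (one transformer layer)
#'
#' Attention with queries = keys = values = the input, plus residual
#' connections, layer normalisation and a two-layer feed-forward of width
#' `ffMult * e`; shape-preserving.
#'
#' @param X input sequence, `m x e`.
#' @inheritParams crossAttentionBlock
#' @return Matrix of the same shape as `X`.
#' @export
selfAttentionBlock <- function(X, cfg = attentionConfig(e = ncol(X)),
                               params = NULL, seed = 1L, train = FALSE) {
  X <- as.matrix(X) # force before any seeded draws
  if (is.null(params))
    params <- withSeed(deriveSeed(seed, "self"),
                       blockInit(ncol(X), ncol(X), cfg$dk, cfg$ffMult))
  blockFwd(X, X, params, cfg$nHeads, cfg$dropout, train)$out
}

#' Perceiver encoder
#'
#' Adds positional encoding to the input, applies `M` cross-attentions of the
#' latents with the input (averaged), then `N` self-attention layers on the
#' `l x latentDim` result.
#'
#' @param X input sequence, `T x e`.
#' @param cfg an [attentionConfig()].
#' @param params optional full parameter tree from `initPerceiverParams`;
#'   initialised from `seed` when omitted (latents included).
#' @param seed seed for parameter initialisation.
#' @param train logical; enables dropout.
#' @return `l x latentDim` encoded matrix.
#' @export
perceiverEncode <- function(X, cfg = attentionConfig(e = ncol(X)),
                            params = NULL, seed = 1L, train = FALSE) {
  if (ncol(X) != cfg$e) stop("input width must equal cfg$e")
  if (is.null(params))
    params <- withSeed(deriveSeed(seed, "perceiver"),
                       initPerceiverParams(cfg, nrow(X)))
  encoderFwd(X, params, cfg, "perceiver", train)$out
}

#' Transformer encoder
#'
#' Identical pipeline to [perceiverEncode()] with the cross-attention stage
#' replaced by self-attention over the input: positional encoding, `M`
#' averaged self-attention blocks, then `N` further self-attention layers.
#'
#' @inheritParams perceiverEncode
#' @return `T x e` encoded matrix.
#' @export
transformerEncode <- function(X, cfg = attentionConfig(e = ncol(X)),
                              params = NULL, seed = 1L, train = FALSE) {
  if (ncol(X) != cfg$e) stop("input width must equal cfg$e")
  if (is.null(params))
    params <- withSeed(deriveSeed(seed, "transformer"),
                       initTransformerParams(cfg, nrow(X)))
  encoderFwd(X, params, cfg, "transformer", train)$out
}

#' Classification head
#'
#' Mean-pools the encoded rows (so the head is independent of the number of
#' latents/time steps and invariant to row order), applies an affine map and
#' a logistic squashing.
#'
#' @param encoded `m x e` encoded matrix.
#' @param params optional list with `w` (length e) and `b`; seeded when
#'   omitted.
#' @param seed seed for parameter initialisation.
#' @return Probability strictly in (0, 1).
#' @export
classifyHead <- function(encoded, params = NULL, seed = 1L) {
  encoded <- as.matrix(encoded) # force before any seeded draws
  if (is.null(params))
    params <- withSeed(deriveSeed(seed, "head"), headInit(ncol(encoded)))
  headFwd(encoded, params)$prob
}
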