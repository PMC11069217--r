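## Analytic FLOP accounting for the attention encoders. Conventions (fixed
## and documented): one multiply-accumulate = 2 flops; a bias add, residual
## add or elementwise activation = 1 flop per element; softmax = 5 flops per
## score entry (max-subtract, exp, sum, divide); layer normalisation = 8
## flops per element. Counts are per patient per forward pass; batches scale
## multiplicatively. These conventions make orderings and crossovers
## meaningful; absolute totals depend on the convention.

linFlops <- function(n, din, dout, bias = TRUE) {
  2 * n * din * dout + if (bias) n * dout else 0
}

blockFlops <- function(q, k, wq, wkv, dk, ffMult) {
  ff <- ffMult * wq
  c(proj_q = linFlops(q, wq, dk, FALSE),
    proj_kv = 2 * linFlops(k, wkv, dk, FALSE),
    attn_scores = 2 * q * k * dk,
    softmax = 5 * q * k,
    attn_values = 2 * q * k * dk,
    proj_out = linFlops(q, dk, wq),
    residual1 = q * wq,
    layernorm1 = 8 * q * wq,
    feedforward = linFlops(q, wq, ff) + q * ff + linFlops(q, ff, wq),
    residual2 = q * wq,
    layernorm2 = 8 * q * wq)
}

blockStored <- function(q, k, dk) {
  ## stored Q + K + V projections and the attention score matrix
  q * dk + 2 * k * dk + q * k
}

#' Analytic FLOP count for one encoder forward pass
#'
#' Counts exact multiply-accumulate (and elementwise) operations for the
#' Perceiver or transformer encoder on one patient, using the package's
#' fixed layer definitions (identical block internals for both kinds, so
#' the comparison is apples-to-apples). The embedding MLP and classifier
#' head are itemised separately so either inclusion convention can be read
#' off. Counts are pure functions of the configuration.
#'
#' @param kind `"perceiver"` or `"transformer"`.
#' @param T sequence length.
#' @param cfg an [attentionConfig()]; `cfg$l` defaults to `T`.
#' @param D optional raw feature count; when given, the embedding MLP
#'   (hidden width `embedHidden`) is itemised.
#' @param embedHidden embedding hidden width (default 32).
#' @return A [FlopsReport].
#' @export
countFlops <- function(kind = c("perceiver", "transformer"), T,
                       cfg = attentionConfig(), D = NULL,
                       embedHidden = 32L) {
  kind <- match.arg(kind)
  if (T < 1L) stop("dimensions must be positive")
  e <- cfg$e
  l <- if (is.null(cfg$l)) T else cfg$l
  if (l < 1L || e < 1L || cfg$dk < 1L) stop("dimensions must be positive")
  L <- cfg$latentDim
  comp <- c(positional_encoding = T * e)
  if (!is.null(D))
    comp <- c(embedding = linFlops(T, D, embedHidden) + T * embedHidden +
                linFlops(T, embedHidden, e), comp)
  stored <- 0
  if (kind == "perceiver") {
    for (m in seq_len(cfg$M)) {
      b <- blockFlops(l, T, L, e, cfg$dk, cfg$ffMult)
      names(b) <- paste0("cross", m, "_", names(b))
      comp <- c(comp, b)
      stored <- stored + blockStored(l, T, cfg$dk)
    }
    if (cfg$M > 1L) comp <- c(comp, cross_average = (cfg$M) * l * L)
    for (nn in seq_len(cfg$N)) {
      b <- blockFlops(l, l, L, L, cfg$dk, cfg$ffMult)
      names(b) <- paste0("self", nn, "_", names(b))
      comp <- c(comp, b)
      stored <- stored + blockStored(l, l, cfg$dk)
    }
    headW <- L
    mHead <- l
  } else {
    for (m in seq_len(cfg$M + cfg$N)) {
      b <- blockFlops(T, T, e, e, cfg$dk, cfg$ffMult)
      names(b) <- paste0("self", m, "_", names(b))
      comp <- c(comp, b)
      stored <- stored + blockStored(T, T, cfg$dk)
    }
    headW <- e
    mHead <- T
  }
  comp <- c(comp, classifier = mHead * headW + 2 * headW + 2)
  counts <- data.frame(component = names(comp), flops = as.numeric(comp),
                       row.names = NULL)
  new("FlopsReport", counts = counts, total = sum(counts$flops),
      stored = stored,
      config = list(kind = kind, T = T, e = e, l = l, latentDim = L,
                    dk = cfg$dk, nHeads = cfg$nHeads, M = cfg$M, N = cfg$N,
                    D = D))
}

#' FLOP sweep over the number of latents
#'
#' Compares the Perceiver total against the transformer total (a horizontal
#' reference independent of `l`) for each requested latent count.
#'
#' @param T sequence length.
#' @param cfg an [attentionConfig()]; its `l` field is overridden by the
#'   sweep.
#' @param ls latent counts to evaluate (default `1:T`).
#' @param D optional raw feature count (embedding itemised when given).
#' @return data.frame with columns `l`, `perceiver`, `transformer`, `ratio`
#'   (transformer / perceiver).
#' @export
latentSweep <- function(T, cfg = attentionConfig(), ls = seq_len(T),
                        D = NULL) {
  if (any(ls < 1L | ls > T)) stop("latent counts must lie in 1..T")
  tf <- countFlops("transformer", T, cfg, D)@total
  pv <- vapply(ls, function(l) {
    c2 <- cfg; c2$l <- as.integer(l)
    countFlops("perceiver", T, c2, D)@total
  }, numeric(1))
  data.frame(l = ls, perceiver = pv, transformer = tf, ratio = tf / pv)
}
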