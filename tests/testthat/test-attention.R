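test_that("scaled dot-product attention matches hand-derived cases", {
  ## equal scores -> uniform weights
  r <- scaledDotProductAttention(matrix(0, 1, 2), matrix(0, 2, 2),
                                 matrix(c(1, 5, 3, 7), 2, 2))
  expect_equal(r$weights, matrix(0.5, 1, 2))
  expect_equal(r$output, matrix(c(3, 5), 1, 2))
  ## one informative key: sigma = exp(1/sqrt(2)) / (exp(1/sqrt(2)) + 1)
  sig <- exp(1 / sqrt(2)) / (exp(1 / sqrt(2)) + 1)
  r <- scaledDotProductAttention(matrix(c(1, 0), 1, 2), diag(2), diag(2))
  expect_equal(r$weights, matrix(c(sig, 1 - sig), 1, 2), tolerance = 1e-12)
  expect_equal(r$output, matrix(c(sig, 1 - sig), 1, 2), tolerance = 1e-12)
  ## weight rows always normalise
  set.seed(2)
  r <- scaledDotProductAttention(matrix(rnorm(40), 5, 8),
                                 matrix(rnorm(40), 5, 8),
                                 matrix(rnorm(15), 5, 3))
  expect_equal(rowSums(r$weights), rep(1, 5), tolerance = 1e-6)
  expect_error(scaledDotProductAttention(matrix(0, 1, 3), diag(2), diag(2)),
               "d_k")
  expect_error(scaledDotProductAttention(matrix(0, 1, 2), diag(2),
                                         matrix(0, 3, 2)), "row count")
})

test_that("attention outputs stay inside the value rows' convex envelope", {
  set.seed(3)
  for (i in 1:25) {
    V <- matrix(rnorm(12), 4, 3)
    r <- scaledDotProductAttention(matrix(rnorm(10), 2, 5),
                                   matrix(rnorm(20), 4, 5), V)
    for (j in 1:3) {
      expect_gte(min(r$output[, j]), min(V[, j]) - 1e-12)
      expect_lte(max(r$output[, j]), max(V[, j]) + 1e-12)
    }
  }
})

test_that("positional encoding matches its closed form", {
  pe <- positionalEncoding(48, 128)
  ## independent double-loop evaluation
  for (pos in c(0, 1, 7, 47)) {
    for (i in c(0, 1, 31, 63)) {
      expect_equal(pe[pos + 1, 2 * i + 1], sin(pos / 10000^(2 * i / 128)),
                   tolerance = 1e-12)
      expect_equal(pe[pos + 1, 2 * i + 2], cos(pos / 10000^(2 * i / 128)),
                   tolerance = 1e-12)
    }
  }
  expect_true(all(pe[1, seq(1, 127, by = 2)] == 0)) # sin(0)
  expect_true(all(pe[1, seq(2, 128, by = 2)] == 1)) # cos(0)
  expect_equal(pe[2, 1], sin(1), tolerance = 1e-9)
  expect_true(all(pe >= -1 & pe <= 1))
  expect_error(positionalEncoding(10, 7), "even")
})

test_that("cross-attention squeezes T steps into l latents and averages over M", {
  cfg <- tinyAttnCfg(e = 32L)
  X <- matrix(rnorm(48 * 32), 48, 32)
  Z <- latentBank(4, 32, seed = 1)
  out <- crossAttentionBlock(X, Z, cfg, seed = 5)
  expect_equal(dim(out), c(4L, 32L))
  ## M = 2 with tied parameters equals M = 1 (mean of identical terms)
  p1 <- withr::with_seed(1, cperceiver:::blockInit(32L, 32L, cfg$dk, cfg$ffMult))
  cfg2 <- cfg; cfg2$M <- 2L
  out1 <- crossAttentionBlock(X, Z, cfg, params = list(p1))
  out2 <- crossAttentionBlock(X, Z, cfg2, params = list(p1, p1))
  expect_equal(out1, out2, tolerance = 1e-12)
  expect_error(crossAttentionBlock(X[, 1:10], Z, cfg), "width")
})

test_that("self-attention block preserves shape and is permutation-equivariant", {
  cfg <- tinyAttnCfg(e = 32L)
  X <- matrix(rnorm(5 * 32), 5, 32)
  p <- withr::with_seed(2, cperceiver:::blockInit(32L, 32L, cfg$dk, cfg$ffMult))
  out <- selfAttentionBlock(X, cfg, params = p)
  expect_equal(dim(out), dim(X))
  perm <- c(3, 1, 5, 2, 4)
  outPerm <- selfAttentionBlock(X[perm, ], cfg, params = p)
  expect_equal(outPerm, out[perm, ], tolerance = 1e-10)
  ## deterministic with dropout 0
  expect_identical(out, selfAttentionBlock(X, cfg, params = p))
})

test_that("perceiver encoder honours latent count and the N=0 boundary", {
  X <- matrix(rnorm(12 * 6), 12, 6)
  cfgT <- tinyAttnCfg(l = 12L)
  expect_equal(dim(perceiverEncode(X, cfgT, seed = 3)), c(12L, 6L))
  cfg1 <- tinyAttnCfg(l = 1L)
  expect_equal(dim(perceiverEncode(X, cfg1, seed = 3)), c(1L, 6L))
  ## N = 0: output equals the averaged cross-attention on the encoded input
  cfg0 <- tinyAttnCfg(l = 4L, N = 0L)
  params <- withr::with_seed(4, cperceiver:::initPerceiverParams(cfg0, 12L))
  enc <- perceiverEncode(X, cfg0, params = params)
  Xp <- X + positionalEncoding(12, 6)
  expect_equal(enc, crossAttentionBlock(Xp, params$Z, cfg0,
                                        params = params$cross),
               tolerance = 1e-12)
})

test_that("transformer encoder shares the pipeline with self-attention queries", {
  X <- matrix(rnorm(10 * 6), 10, 6)
  cfg <- tinyAttnCfg()
  out <- transformerEncode(X, cfg, seed = 6)
  expect_equal(dim(out), c(10L, 6L))
  expect_identical(out, transformerEncode(X, cfg, seed = 6))
})

test_that("latents of a different width than the input are supported end-to-end", {
  cfg <- attentionConfig(e = 8L, dk = 16L, l = 3L, latentDim = 12L, dropout = 0)
  X <- matrix(rnorm(20 * 8), 20, 8)
  out <- perceiverEncode(X, cfg, seed = 9)
  expect_equal(dim(out), c(3L, 12L))
})

test_that("classifier head pools, squashes, and ignores row order", {
  H <- matrix(rnorm(7 * 6), 7, 6)
  expect_equal(classifyHead(H, params = list(w = rep(0, 6), b = 0)), 0.5)
  p <- classifyHead(H, seed = 2)
  expect_gt(p, 0); expect_lt(p, 1)
  expect_equal(classifyHead(H[sample(7), ], seed = 2), p, tolerance = 1e-12)
})

test_that("attention config invariants are enforced", {
  expect_error(attentionConfig(dk = 10L, nHeads = 3L), "divisible")
  expect_error(attentionConfig(l = 0L), "latent")
  expect_error(attentionConfig(dropout = 1), "dropout")
})
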