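#' @importFrom stats rnorm runif plogis setNames quantile
#' @importFrom utils head tail
#' @importFrom data.table fread fwrite dcast rbindlist data.table
NULL

.datatable.aware <- TRUE

#' Derive a substream seed from a root seed and a stream name
#'
#' All randomness in the package flows from one root seed through named
#' substreams (e.g. "data", "init", "dropout", "mc"), so that changing one
#' stage's draws never perturbs another's.
#'
#' @param seed integer root seed.
#' @param stream character stream name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
deriveSeed <- function(seed, stream) {
  stopifnot(is.character(stream), length(stream) == 1L)
  codes <- utf8ToInt(stream)
  h <- sum(codes * seq_along(codes)) %% 2147483647
  as.integer((abs(as.numeric(seed)) * 48271 + h * 9973 + 17) %% 2147483629)
}

## Evaluate expr with a temporary RNG state seeded at `seed`, restoring the
## caller's state afterwards.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483629))
  force(expr)
}

sigmoid <- function(x) plogis(x)

## Row-wise softmax with max-subtraction for numerical stability.
softmaxRows <- function(x) {
  m <- apply(x, 1L, max)
  e <- exp(x - m)
  e / rowSums(e)
}

## ---- parameter trees -------------------------------------------------------
## Model parameters are nested named lists whose leaves are numeric matrices
## or vectors; these walkers apply a function leaf-wise across parallel trees.

treeMap <- function(f, a, b = NULL, c = NULL) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    for (i in seq_along(a))
      out[[i]] <- treeMap(f, a[[i]], if (!is.null(b)) b[[i]], if (!is.null(c)) c[[i]])
    out
  } else {
    if (is.null(b)) f(a) else if (is.null(c)) f(a, b) else f(a, b, c)
  }
}

treeZero <- function(a) treeMap(function(x) x * 0, a)

treeSumSq <- function(a) {
  s <- 0
  treeMap(function(x) { s <<- s + sum(x^2); x }, a)
  s
}

## ---- Adam optimiser --------------------------------------------------------

adamInit <- function(params) {
  list(m = treeZero(params), v = treeZero(params), t = 0L)
}

adamStep <- function(params, grads, state, lr = 1e-4,
                     beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  state$m <- treeMap(function(m, g) beta1 * m + (1 - beta1) * g, state$m, grads)
  state$v <- treeMap(function(v, g) beta2 * v + (1 - beta2) * g^2, state$v, grads)
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  params <- treeMap(function(p, m, v) p - lr * (m / c1) / (sqrt(v / c2) + eps),
                    params, state$m, state$v)
  list(params = params, state = state)
}

## Gaussian-initialised matrix; consumes the current RNG stream.
initMat <- function(nr, nc, sd = NULL) {
  if (is.null(sd)) sd <- sqrt(2 / (nr + nc))
  matrix(rnorm(nr * nc, sd = sd), nr, nc)
}

## Add a length-nc bias vector to every row of an n x nc matrix.
addBias <- function(x, b) x + rep(b, each = nrow(x))
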