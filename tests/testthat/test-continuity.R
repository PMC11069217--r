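test_that("series embedding is a row-wise map with the expected shape", {
  emb <- seriesEmbedding(D = 8L, e = 32L, seed = 1)
  X <- matrix(rnorm(80), 10, 8)
  E <- embedSeries(X, emb)
  expect_equal(dim(E), c(10L, 32L))
  ## identical rows map identically
  X2 <- X; X2[3, ] <- X2[7, ]
  E2 <- embedSeries(X2, emb)
  expect_identical(E2[3, ], E2[7, ])
  ## zeroed parameters give zero output (linear output layer)
  emb0 <- emb
  emb0$params <- cperceiver:::treeZero(emb0$params)
  expect_equal(embedSeries(X, emb0), matrix(0, 10, 32))
})

test_that("ode solver reproduces constant and exponential dynamics", {
  zero <- derivativeField(e = 2L, hidden = c(4L, 4L), initSd = 0, seed = 1)
  tr <- odeSolve(zero, c(1, 2), times = c(0, 1, 2),
                 solver = solverConfig(method = "rk4"))
  expect_equal(tr$states, matrix(c(1, 2), 3, 2, byrow = TRUE))
  ## scalar f(z) = z reaches e at t = 1 (adaptive Dormand-Prince)
  tr <- odeSolve(function(z, t) z, 1, times = c(0, 1),
                 solver = solverConfig(rtol = 1e-3, atol = 1e-4))
  expect_equal(tr$states[2, 1], exp(1), tolerance = 1e-3)
  expect_identical(tr$states[1, 1], 1) # initial condition is exact
  expect_error(odeSolve(function(z, t) z, 1, times = c(1, 0.5)), "increasing")
})

test_that("fixed-step RK4 agrees with the adaptive deSolve oracle", {
  a <- c(-0.8, 0.3, 0.1)
  f <- function(z, t) a * z
  times <- seq(0, 2, by = 0.25)
  rk <- odeSolve(f, c(1, -1, 2), times,
                 solverConfig(method = "rk4", stepsPerInterval = 4L))
  dp <- odeSolve(f, c(1, -1, 2), times,
                 solverConfig(rtol = 1e-8, atol = 1e-10))
  expect_equal(rk$states, dp$states, tolerance = 1e-5)
})

test_that("linear diagonal field matches elementwise exponentials on the 48-step grid", {
  a <- c(-1.2, 0.6)
  f <- function(z, t) a * z
  times <- (0:47) / 48
  rtol <- 1e-3
  tr <- odeSolve(f, c(1, 1), times,
                 solverConfig(method = "rk4", stepsPerInterval = 1L))
  truth <- cbind(exp(a[1] * times), exp(a[2] * times))
  expect_lt(max(abs(tr$states - truth) / pmax(abs(truth), 1)), 10 * rtol)
})

test_that("continuous resampling degenerates to carry-forward under a zero field", {
  emb <- seriesEmbedding(D = 3L, e = 6L, seed = 2)
  zero <- derivativeField(e = 6L, hidden = c(8L, 8L), initSd = 0, seed = 1)
  s <- patientSeries("p", c(0, 3), matrix(rnorm(6), 2, 3))
  ## full mode: every row equals the embedded first observation
  full <- continuousResample(s, 0:4, "full", zero, emb)
  E <- embedSeries(s, emb)
  for (j in 1:5)
    expect_equal(seriesValues(full)[j, ], E[1, ], tolerance = 1e-12)
  ## fill mode: gaps carry the most recent embedded observation
  fill <- continuousResample(s, 0:4, "fill", zero, emb)
  cf <- embedSeries(carryForwardFill(s, 0:4), emb)
  expect_equal(unname(seriesValues(fill)), unname(cf), tolerance = 1e-10)
  ## fill mode with nothing missing returns the embedded observations exactly
  dense <- patientSeries("p", 0:4, matrix(rnorm(15), 5, 3))
  out <- continuousResample(dense, 0:4, "fill", zero, emb)
  expect_equal(unname(seriesValues(out)),
               unname(embedSeries(dense, emb)), tolerance = 1e-12)
  expect_error(continuousResample(patientSeries("p", 1.5, matrix(1, 1, 3)),
                                  0:4, "fill", zero, emb), "on the grid")
})

test_that("a learned field halves held-out resampling error versus carry-forward", {
  ## Noiseless cohort whose latent dynamics are a shared 0.5 rad/h rotation
  ## (linear, class-unambiguous, and badly served by carry-forward). The
  ## derivative field is trained by regressing the full-mode trajectory
  ## (generated from the first observation; identity embedding, so dynamics
  ## live in the raw feature space) on the odd-numbered steps; the even
  ## steps are held out and the fill-mode resample is compared against
  ## carry-forward imputation of the same observations.
  T <- 16L; D <- 2L
  rot <- 0.5 * matrix(c(0, -1, 1, 0), 2, 2)
  dyn <- list(A0 = rot, A1 = rot, b0 = c(0, 0), b1 = c(0, 0),
              mean0 = c(0, 0), mean1 = c(0, 0), initSd = 0.5)
  coh <- generateCohort(cohortSpec(n = 16, T = T, D = D, noiseSd = 0,
                                   missingRate = 0, seed = 21,
                                   dynamics = dyn))
  sers <- cohortSeries(coh)
  B <- length(sers)
  heldOut <- seq(2, T, by = 2)
  obsIdx <- setdiff(seq_len(T), heldOut)
  truth <- lapply(sers, seriesValues)
  Elist <- lapply(truth, function(m) m[obsIdx, ])
  obsRow <- matrix(NA_integer_, B, T)
  obsRow[, obsIdx] <- matrix(rep(seq_along(obsIdx), each = B), B)
  scaled <- (0:(T - 1)) / T
  params <- withr::with_seed(3, lapply(
    list(c(D + 1L, 32L), c(32L, 32L), c(32L, D)),
    function(w) list(W = cperceiver:::initMat(w[1], w[2]),
                     b = rep(0, w[2]))))
  state <- cperceiver:::adamInit(params)
  trainRow <- matrix(NA_integer_, B, T) # full mode: no resets during training
  for (it in 1:1200) {
    fw <- cperceiver:::resampleFwd(trainRow, Elist, params, "full", scaled)
    dOut <- array(0, dim = c(B, T, D))
    for (b in seq_len(B))
      dOut[b, obsIdx, ] <- (fw$out[b, obsIdx, ] - truth[[b]][obsIdx, ]) / B
    acc <- new.env(); acc$g <- cperceiver:::treeZero(params)
    cperceiver:::resampleBwd(dOut, fw, Elist, params, NULL, acc)
    upd <- cperceiver:::adamStep(params, acc$g, state, lr = 2e-2)
    params <- upd$params; state <- upd$state
  }
  fw <- cperceiver:::resampleFwd(obsRow, Elist, params, "fill", scaled)
  mseNode <- mean(vapply(seq_len(B), function(b)
    mean((fw$out[b, heldOut, ] - truth[[b]][heldOut, ])^2), numeric(1)))
  mseCF <- mean(vapply(seq_len(B), function(b) {
    cf <- seriesValues(carryForwardFill(
      patientSeries("x", obsIdx - 1, Elist[[b]]), 0:(T - 1)))
    mean((cf[heldOut, ] - truth[[b]][heldOut, ])^2)
  }, numeric(1)))
  expect_lt(mseNode, 0.5 * mseCF)
})

test_that("solver and field constructors validate their arguments", {
  expect_error(solverConfig(rtol = 0), "positive")
  expect_error(continuousResample(patientSeries("p", 5, matrix(1, 1, 2)),
                                  0:4, "full",
                                  derivativeField(4L, c(4L), initSd = 0),
                                  seriesEmbedding(2L, 4L)), NA)
})
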