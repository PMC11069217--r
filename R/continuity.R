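#' ODE solver configuration
#'
#' @param method `"dopri5"` (adaptive Dormand-Prince, via deSolve; the
#'   default for inference-style solves) or `"rk4"` (fixed-step classical
#'   Runge-Kutta; the differentiable solver used inside training).
#' @param rtol,atol relative/absolute tolerances for the adaptive method.
#' @param maxSteps maximum internal steps before an integration-failure error.
#' @param stepsPerInterval fixed RK4 sub-steps between consecutive requested
#'   times.
#' @return A list of class `"solverConfig"`.
#' @export
solverConfig <- function(method = c("dopri5", "rk4"), rtol = 1e-3, atol = 1e-4,
                         maxSteps = 10000L, stepsPerInterval = 1L) {
  method <- match.arg(method)
  if (rtol <= 0 || atol <= 0) stop("tolerances must be positive")
  structure(list(method = method, rtol = rtol, atol = atol,
                 maxSteps = as.integer(maxSteps),
                 stepsPerInterval = as.integer(stepsPerInterval)),
            class = "solverConfig")
}

#' Neural derivative field f(Z, t) for the patient-state ODE
#'
#' A multilayer perceptron parameterising the derivative of the patient
#' state: input `(Z, t)` (time appended as one extra input), three hidden
#' tanh layers of 128 units by default, linear output of width `e`.
#' `initSd = 0` gives the exactly-zero field (useful for degenerate-limit
#' checks).
#'
#' @param e state width.
#' @param hidden integer vector of hidden-layer widths.
#' @param dropout dropout rate applied to hidden activations during training;
#'   the mask is sampled once per solve and held fixed across derivative
#'   evaluations so each forward pass integrates a well-defined ODE.
#' @param seed integer seed for initialisation.
#' @param initSd optional fixed init scale overriding the default
#'   `sqrt(2/(fanIn+fanOut))`; `0` zeroes all parameters.
#' @return A list of class `"derivativeField"`.
#' @export
derivativeField <- function(e, hidden = c(128L, 128L, 128L), dropout = 0.5,
                            seed = 1L, initSd = NULL) {
  widths <- c(e + 1L, hidden, e)
  params <- withSeed(deriveSeed(seed, "field"), {
    lapply(seq_len(length(widths) - 1L), function(i)
      list(W = initMat(widths[i], widths[i + 1L], initSd),
           b = rep(0, widths[i + 1L])))
  })
  structure(list(params = params, e = as.integer(e),
                 hidden = as.integer(hidden), dropout = dropout),
            class = "derivativeField")
}

## Field forward on a batch: Z is B x e, t scalar (already on the scaled time
## axis). masks: NULL or list of B x width dropout masks per hidden layer.
fieldFwd <- function(Z, t, params, masks = NULL) {
  nL <- length(params)
  x <- cbind(Z, t)
  caches <- vector("list", nL)
  for (i in seq_len(nL - 1L)) {
    a <- tanh(addBias(x %*% params[[i]]$W, params[[i]]$b))
    caches[[i]] <- list(x = x, a = a)
    x <- if (is.null(masks)) a else a * masks[[i]]
  }
  out <- addBias(x %*% params[[nL]]$W, params[[nL]]$b)
  caches[[nL]] <- list(x = x)
  list(out = out, caches = caches)
}

## Backward through one field evaluation; accumulates parameter grads into
## the environment `acc` (a list `acc$g` shaped like params) and returns dZ.
fieldBwd <- function(dOut, cache, params, masks, acc) {
  nL <- length(params)
  dy <- dOut # gradient w.r.t. the pre-activation output of layer i
  g <- acc$g
  for (i in rev(seq_len(nL))) {
    cc <- cache$caches[[i]]
    g[[i]]$W <- g[[i]]$W + crossprod(cc$x, dy)
    g[[i]]$b <- g[[i]]$b + colSums(dy)
    if (i > 1L) {
      dh <- dy %*% t(params[[i]]$W)
      if (!is.null(masks)) dh <- dh * masks[[i - 1L]]
      dy <- dh * (1 - cache$caches[[i - 1L]]$a^2)
    }
  }
  acc$g <- g
  dx <- dy %*% t(params[[1L]]$W)
  dx[, seq_len(ncol(dOut)), drop = FALSE]
}

## One classical RK4 step for the whole batch from t to t + h.
rk4StepFwd <- function(Z, t, h, params, masks) {
  k1 <- fieldFwd(Z, t, params, masks)
  k2 <- fieldFwd(Z + h / 2 * k1$out, t + h / 2, params, masks)
  k3 <- fieldFwd(Z + h / 2 * k2$out, t + h / 2, params, masks)
  k4 <- fieldFwd(Z + h * k3$out, t + h, params, masks)
  Znew <- Z + h / 6 * (k1$out + 2 * k2$out + 2 * k3$out + k4$out)
  list(Z = Znew, Z0 = Z, h = h, k1 = k1, k2 = k2, k3 = k3, k4 = k4)
}

rk4StepBwd <- function(dZnew, step, params, masks, acc) {
  h <- step$h
  dZ <- dZnew
  dk1 <- h / 6 * dZnew
  dk2 <- 2 * h / 6 * dZnew
  dk3 <- 2 * h / 6 * dZnew
  dk4 <- h / 6 * dZnew
  dIn4 <- fieldBwd(dk4, step$k4, params, masks, acc)
  dZ <- dZ + dIn4
  dk3 <- dk3 + h * dIn4
  dIn3 <- fieldBwd(dk3, step$k3, params, masks, acc)
  dZ <- dZ + dIn3
  dk2 <- dk2 + h / 2 * dIn3
  dIn2 <- fieldBwd(dk2, step$k2, params, masks, acc)
  dZ <- dZ + dIn2
  dk1 <- dk1 + h / 2 * dIn2
  dIn1 <- fieldBwd(dk1, step$k1, params, masks, acc)
  dZ + dIn1
}

## ---- batched continuous resampling ----------------------------------------
## obsRow: B x T integer matrix; obsRow[b, j] is the row index of patient b's
## embedded observation at grid step j, or NA when step j is unobserved.
## Elist: per-patient t_d x e embedded observation matrices.
## Returns states as a B x T x e array plus the caches needed for backward.

resampleFwd <- function(obsRow, Elist, params, mode, scaledTimes,
                        nsub = 1L, masks = NULL) {
  B <- length(Elist)
  T <- length(scaledTimes)
  e <- ncol(Elist[[1L]])
  Z <- do.call(rbind, lapply(Elist, function(E) E[1L, ]))
  out <- array(0, dim = c(B, T, e))
  out[, 1L, ] <- Z
  intervals <- vector("list", T - 1L)
  for (j in seq_len(T - 1L)) {
    t0 <- scaledTimes[j]
    h <- (scaledTimes[j + 1L] - t0) / nsub
    steps <- vector("list", nsub)
    for (s in seq_len(nsub)) {
      steps[[s]] <- rk4StepFwd(Z, t0 + (s - 1L) * h, h, params, masks)
      Z <- steps[[s]]$Z
    }
    out[, j + 1L, ] <- Z
    reset <- integer(0)
    if (mode == "fill") {
      reset <- which(!is.na(obsRow[, j + 1L]))
      for (b in reset) {
        row <- Elist[[b]][obsRow[b, j + 1L], ]
        out[b, j + 1L, ] <- row
        Z[b, ] <- row
      }
    }
    intervals[[j]] <- list(steps = steps, reset = reset)
  }
  list(out = out, intervals = intervals, obsRow = obsRow)
}

resampleBwd <- function(dOut, cache, Elist, params, masks, acc) {
  B <- dim(dOut)[1L]
  T <- dim(dOut)[2L]
  e <- dim(dOut)[3L]
  dE <- lapply(Elist, function(E) E * 0)
  dZ <- matrix(0, B, e)
  for (j in rev(seq_len(T - 1L))) {
    iv <- cache$intervals[[j]]
    dStep <- matrix(dOut[, j + 1L, ], B, e)
    for (b in iv$reset) {
      row <- cache$obsRow[b, j + 1L]
      dE[[b]][row, ] <- dE[[b]][row, ] + dStep[b, ] + dZ[b, ]
      dStep[b, ] <- 0
      dZ[b, ] <- 0
    }
    dZ <- dZ + dStep
    for (s in rev(seq_along(iv$steps)))
      dZ <- rk4StepBwd(dZ, iv$steps[[s]], params, masks, acc)
  }
  dZ <- dZ + matrix(dOut[, 1L, ], B, e)
  for (b in seq_len(B)) dE[[b]][1L, ] <- dE[[b]][1L, ] + dZ[b, ]
  dE
}

#' Row-wise series embedding
#'
#' A single-hidden-layer MLP (default width 32, ReLU hidden, linear output)
#' applied independently to every observed time step, mapping `D` raw
#' features to an `e`-dimensional patient-state embedding.
#'
#' @param D raw feature count.
#' @param e embedding width (default 32).
#' @param hidden hidden-layer width (default 32).
#' @param seed integer seed.
#' @return A list of class `"seriesEmbedding"`.
#' @export
seriesEmbedding <- function(D, e = 32L, hidden = 32L, seed = 1L) {
  params <- withSeed(deriveSeed(seed, "embed"), embedInit(D, e, hidden))
  structure(list(params = params, D = as.integer(D), e = as.integer(e),
                 hidden = as.integer(hidden)),
            class = "seriesEmbedding")
}

#' Embed the observed rows of a series
#'
#' @param x a [PatientSeries] or a `t_d x D` numeric matrix.
#' @param embedding a [seriesEmbedding()].
#' @return `t_d x e` matrix of embedded observations.
#' @export
embedSeries <- function(x, embedding) {
  stopifnot(inherits(embedding, "seriesEmbedding"))
  vals <- if (is(x, "PatientSeries")) seriesValues(x) else as.matrix(x)
  if (ncol(vals) != embedding$D) stop("feature count mismatch with embedding")
  embedFwd(vals, embedding$params)$out
}

#' Solve the patient-state ODE at requested times
#'
#' Integrates `dZ/dt = f(Z(t), t)` from the initial state `Z0` and returns
#' one state per requested time (the first state is `Z0` itself).
#'
#' @param field a [derivativeField()] or a plain R function `f(z, t)`
#'   returning `dz/dt`.
#' @param z0 numeric initial state.
#' @param times strictly increasing times; `times[1]` is the initial time.
#' @param solver a [solverConfig()].
#' @return A list of class `"StateTrajectory"` with `times` and a
#'   `length(times) x e` `states` matrix.
#' @export
odeSolve <- function(field, z0, times, solver = solverConfig()) {
  if (!is.numeric(times) || length(times) < 1L)
    stop("times must be a non-empty numeric vector")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  f <- if (inherits(field, "derivativeField")) {
    function(z, t) as.vector(fieldFwd(matrix(z, 1L), t, field$params)$out)
  } else {
    if (!is.function(field)) stop("field must be a derivativeField or function")
    field
  }
  if (solver$method == "rk4") {
    states <- matrix(0, length(times), length(z0))
    states[1L, ] <- z0
    z <- matrix(z0, 1L)
    ff <- function(z, t) matrix(f(as.vector(z), t), 1L)
    for (j in seq_len(length(times) - 1L)) {
      h <- (times[j + 1L] - times[j]) / solver$stepsPerInterval
      for (s in seq_len(solver$stepsPerInterval)) {
        t0 <- times[j] + (s - 1L) * h
        k1 <- ff(z, t0)
        k2 <- ff(z + h / 2 * k1, t0 + h / 2)
        k3 <- ff(z + h / 2 * k2, t0 + h / 2)
        k4 <- ff(z + h * k3, t0 + h)
        z <- z + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      }
      states[j + 1L, ] <- z
    }
  } else {
    sol <- try(deSolve::ode(
      y = z0, times = times, parms = NULL,
      func = function(t, y, parms) list(f(y, t)),
      method = deSolve::rkMethod("rk45dp7"),
      rtol = solver$rtol, atol = solver$atol, maxsteps = solver$maxSteps),
      silent = TRUE)
    if (inherits(sol, "try-error") || nrow(sol) < length(times) ||
        anyNA(sol[, -1L]))
      stop("integration failure: solver diverged or exceeded maxSteps")
    states <- unname(as.matrix(sol[, -1L, drop = FALSE]))
  }
  structure(list(times = times, states = states), class = "StateTrajectory")
}

#' @export
print.StateTrajectory <- function(x, ...) {
  cat(sprintf("StateTrajectory: %d states of width %d, t in [%g, %g]\n",
              nrow(x$states), ncol(x$states), min(x$times), max(x$times)))
  invisible(x)
}

#' Resample an irregular series on a regular grid via the patient-state ODE
#'
#' Embeds the observed rows and integrates the derivative field (fixed-step
#' RK4 on times scaled by the grid length, the package's differentiable
#' solver) to produce one `e`-dimensional state per grid time. Two modes,
#' matching the two evaluation strategies for continuous patient-state
#' models:
#' \describe{
#'   \item{`full`}{the entire series is generated from the first observed
#'     step's embedding — useful for low irregularity / noisy data;}
#'   \item{`fill`}{observed grid times keep their own embedded observations
#'     and each gap is integrated forward from the most recent observed
#'     step — preferable at high irregularity.}
#' }
#'
#' @param series a [PatientSeries]; in `fill` mode its times must lie on
#'   `grid`.
#' @param grid target regular grid covering the observation window.
#' @param mode `"full"` or `"fill"`.
#' @param field a [derivativeField()] of width `e`.
#' @param embedding a [seriesEmbedding()] mapping `D` features to width `e`.
#' @param solver a [solverConfig()]; `stepsPerInterval` controls the RK4
#'   step density.
#' @return A [RegularSeries] of embedded width `e` on `grid`.
#' @export
continuousResample <- function(series, grid = timeGrid(48L),
                               mode = c("full", "fill"), field, embedding,
                               solver = solverConfig(method = "rk4")) {
  mode <- match.arg(mode)
  stopifnot(is(series, "PatientSeries"), inherits(field, "derivativeField"))
  if (!length(series@times)) stop("empty series")
  checkGrid(grid)
  if (grid[1L] > series@times[1L] + 1e-9)
    stop("grid must start at or before the first observation")
  E <- embedSeries(series, embedding)
  T <- length(grid)
  obsRow <- matrix(NA_integer_, 1L, T)
  gi <- vapply(series@times, function(t) {
    j <- which.min(abs(grid - t))
    if (abs(grid[j] - t) > 1e-6) NA_integer_ else j
  }, integer(1))
  if (mode == "fill" && anyNA(gi))
    stop("fill mode requires observed times to lie on the grid")
  if (!anyNA(gi)) obsRow[1L, gi] <- seq_along(gi)
  rs <- resampleFwd(obsRow, list(E), field$params, mode,
                    scaledTimes = grid / T, nsub = solver$stepsPerInterval)
  vals <- matrix(rs$out[1L, , ], T, ncol(E))
  new("RegularSeries", patientId = series@patientId,
      times = as.numeric(grid), values = vals)
}
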