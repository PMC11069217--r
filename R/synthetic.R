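#' Specification for the synthetic ICU-like cohort generator
#'
#' The generator emulates the structure of an in-hospital-mortality task:
#' an hourly grid of `T` steps (default the first 48 hours of an ICU stay),
#' `D` continuous features, a binary outcome label, and controllable
#' missingness produced by removing whole time steps. Each class follows its
#' own linear latent dynamics `z[t+1] = z[t] + (A_c z[t] + b_c) * dt`,
#' observed with additive Gaussian noise; class separation therefore grows
#' along the stay, loosely mimicking diverging physiology of survivors and
#' non-survivors.
#'
#' Default dynamics: both classes share mild mean reversion
#' (`A = -0.05 I`). The positive class starts with an admission-severity
#' offset of `+0.5` on the first `ceiling(D/2)` features and additionally
#' drifts at `+0.04 / h` on the same features, so the classes differ both at
#' admission and increasingly along the stay. Initial states are
#' `N(mean_c, 0.5^2)` per feature.
#'
#' @param n number of patients.
#' @param T grid length (default 48).
#' @param D feature count (default 8).
#' @param prevalence fraction of positive labels, in (0,1) (default 0.3).
#' @param noiseSd observation noise standard deviation (default 0.25).
#' @param missingRate fraction of time steps removed per patient, in `[0,1)`.
#' @param seed integer root seed.
#' @param dynamics optional list overriding the class dynamics, with elements
#'   `A0`, `A1` (D x D), `b0`, `b1` (length D), `mean0`, `mean1` (length D
#'   initial-state means) and `initSd` (scalar).
#' @return A list of class `"cohortSpec"`.
#' @export
cohortSpec <- function(n, T = 48L, D = 8L, prevalence = 0.3, noiseSd = 0.25,
                       missingRate = 0, seed = 1L, dynamics = NULL) {
  stopifnot(n >= 2L, T >= 2L, D >= 1L)
  if (prevalence <= 0 || prevalence >= 1) stop("prevalence must be in (0, 1)")
  if (noiseSd < 0) stop("noiseSd must be non-negative")
  if (missingRate < 0 || missingRate >= 1) stop("missingRate must be in [0, 1)")
  if (is.null(dynamics)) dynamics <- defaultClassDynamics(D)
  spec <- list(n = as.integer(n), T = as.integer(T), D = as.integer(D),
               prevalence = prevalence, noiseSd = noiseSd,
               missingRate = missingRate, seed = as.integer(seed),
               dynamics = dynamics)
  class(spec) <- "cohortSpec"
  spec
}

#' @rdname cohortSpec
#' @export
defaultClassDynamics <- function(D) {
  sick <- seq_len(ceiling(D / 2))
  b1 <- numeric(D)
  b1[sick] <- 0.04
  m1 <- numeric(D)
  m1[sick] <- 0.5
  list(A0 = diag(-0.05, D), A1 = diag(-0.05, D),
       b0 = numeric(D), b1 = b1,
       mean0 = numeric(D), mean1 = m1, initSd = 0.5)
}

## Noiseless class-mean trajectory under the linear dynamics: T x D matrix.
classMeanTrajectory <- function(dyn, class, T, dt = 1) {
  A <- if (class == 1L) dyn$A1 else dyn$A0
  b <- if (class == 1L) dyn$b1 else dyn$b0
  z <- if (class == 1L) dyn$mean1 else dyn$mean0
  out <- matrix(0, T, length(z))
  out[1L, ] <- z
  for (t in seq_len(T - 1L)) {
    z <- z + (as.vector(A %*% z) + b) * dt
    out[t + 1L, ] <- z
  }
  out
}

#' Generate a labelled synthetic cohort
#'
#' Exactly `round(prevalence * n)` patients are positive (labels assigned
#' deterministically, then shuffled by seed, so counts are exact rather than
#' binomial). Each patient's latent trajectory follows its class's linear
#' dynamics, is observed with additive Gaussian noise, and is then thinned by
#' [dropTimeSteps()] at `missingRate`. Identical specs yield identical
#' cohorts.
#'
#' @param spec a [cohortSpec()].
#' @return A [PatientCohort] whose metadata records the generator settings.
#' @export
generateCohort <- function(spec) {
  stopifnot(inherits(spec, "cohortSpec"))
  n <- spec$n; T <- spec$T; D <- spec$D
  nPos <- round(spec$prevalence * n)
  if (nPos < 1L || nPos > n - 1L)
    stop("prevalence leaves a single-class cohort at this n")
  labels <- c(rep(1L, nPos), rep(0L, n - nPos))
  labels <- withSeed(deriveSeed(spec$seed, "labels"), sample(labels))
  ids <- sprintf("p%04d", seq_len(n))
  dt <- 1
  vals <- withSeed(deriveSeed(spec$seed, "trajectories"), {
    x <- array(0, dim = c(n, T, D))
    for (cls in c(0L, 1L)) {
      rows <- which(labels == cls)
      if (!length(rows)) next
      dyn <- spec$dynamics
      A <- if (cls == 1L) dyn$A1 else dyn$A0
      b <- if (cls == 1L) dyn$b1 else dyn$b0
      m <- if (cls == 1L) dyn$mean1 else dyn$mean0
      z <- matrix(rnorm(length(rows) * D, sd = dyn$initSd), length(rows), D) +
        rep(m, each = length(rows))
      x[rows, 1L, ] <- z
      for (t in seq_len(T - 1L)) {
        z <- z + (z %*% t(A) + rep(b, each = nrow(z))) * dt
        x[rows, t + 1L, ] <- z
      }
    }
    if (spec$noiseSd > 0)
      x <- x + array(rnorm(length(x), sd = spec$noiseSd), dim = dim(x))
    x
  })
  grid <- timeGrid(T, dt)
  series <- lapply(seq_len(n), function(i) {
    m <- matrix(vals[i, , ], T, D)
    colnames(m) <- paste0("f", seq_len(D))
    s <- patientSeries(ids[i], grid, m)
    if (spec$missingRate > 0)
      s <- dropTimeSteps(s, spec$missingRate, deriveSeed(spec$seed, ids[i]))
    s
  })
  patientCohort(series, labels,
                metadata = list(generator = spec))
}

#' Bayes-motivated oracle score for generated cohorts
#'
#' Projects each patient's last observed row onto the noiseless class-mean
#' difference direction at that time (computed from the generator's known
#' dynamics). Intended purely as a test oracle: on a separable noiseless
#' cohort it ranks classes perfectly.
#'
#' @param cohort a [PatientCohort] produced by [generateCohort()].
#' @return Numeric score per patient (higher = more likely positive).
#' @export
oracleScore <- function(cohort) {
  stopifnot(is(cohort, "PatientCohort"))
  spec <- cohort@metadata$generator
  if (is.null(spec)) stop("cohort lacks generator metadata; oracleScore applies only to synthetic cohorts")
  mu0 <- classMeanTrajectory(spec$dynamics, 0L, spec$T)
  mu1 <- classMeanTrajectory(spec$dynamics, 1L, spec$T)
  grid <- timeGrid(spec$T)
  vapply(cohort@series, function(s) {
    tLast <- length(s@times)
    gi <- which.min(abs(grid - s@times[tLast]))
    d <- mu1[gi, ] - mu0[gi, ]
    sum(s@values[tLast, ] * d)
  }, numeric(1))
}
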