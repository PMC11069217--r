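#' Monte Carlo dropout predictions
#'
#' Evaluates the model `S` times per patient with dropout kept active at
#' inference; the per-patient mean of the draws is the prediction and the
#' variance the predictive uncertainty. With no dropout in the model the
#' draws are identical and the variance is exactly zero (a warning is
#' emitted).
#'
#' @param model a trained `cpsModel`.
#' @param cohort a tagged [PatientCohort].
#' @param split split tag to evaluate (default `"test"`).
#' @param S number of stochastic draws (default 25).
#' @param seed integer seed; results are reproducible given the seed.
#' @return A [PredictionSet].
#' @export
mcDropoutPredict <- function(model, cohort, split = "test", S = 25L,
                             seed = 1L) {
  stopifnot(inherits(model, "cpsModel"), S >= 1L)
  sub <- subsetSplit(cohort, split)
  hasDropout <- model$acfg$dropout > 0 ||
    (isContinuousKind(model$kind) && model$cfg$fieldDropout > 0)
  if (!hasDropout)
    warning("model has no dropout layers; MC draws are deterministic and variance is zero")
  samples <- withSeed(deriveSeed(seed, "mc"), {
    vapply(seq_len(S), function(s)
      predictProb(model, sub, mcDropout = hasDropout),
      numeric(nPatients(sub)))
  })
  samples <- matrix(samples, nPatients(sub), S)
  m <- rowMeans(samples)
  v <- rowMeans(samples^2) - m^2
  v[v < 0] <- 0
  new("PredictionSet", patientId = patientIds(sub), samples = samples,
      mean = m, variance = v, labels = cohortLabels(sub))
}

#' Selective-prediction referral curve
#'
#' Ranks patients by predictive uncertainty (descending), refers the most
#' uncertain fraction to a clinician, and reports the accuracy of the mean
#' prediction (threshold 0.5) on the retained remainder. Ties in
#' uncertainty are broken by stable patient order; `floor(fraction * n)`
#' cases are referred.
#'
#' @param predset a [PredictionSet].
#' @param fractions referral fractions in `[0, 1)` (default 0 to 0.5 in
#'   steps of 0.05).
#' @param uncertainty `"variance"` (default) or a numeric vector of custom
#'   uncertainty scores aligned with the prediction set (e.g. an oracle).
#' @return data.frame with columns `fraction`, `nReferred`, `nRetained`,
#'   `accuracy`.
#' @export
selectivePredictionCurve <- function(predset,
                                     fractions = seq(0, 0.5, by = 0.05),
                                     uncertainty = "variance") {
  stopifnot(is(predset, "PredictionSet"))
  if (any(fractions < 0 | fractions >= 1))
    stop("fractions must lie in [0, 1): referring everyone leaves no case to evaluate")
  u <- if (is.numeric(uncertainty)) {
    if (length(uncertainty) != nrow(predset@samples))
      stop("custom uncertainty must have one value per patient")
    uncertainty
  } else predset@variance
  ord <- order(u, decreasing = TRUE) # ties: stable in patient order
  n <- length(u)
  correct <- (predset@mean >= 0.5) == (predset@labels == 1L)
  do.call(rbind, lapply(fractions, function(f) {
    nRef <- floor(f * n)
    keep <- if (nRef > 0L) ord[-seq_len(nRef)] else seq_len(n)
    data.frame(fraction = f, nReferred = nRef, nRetained = length(keep),
               accuracy = mean(correct[keep]))
  }))
}
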