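#' @import methods
NULL

#' One patient's (possibly irregular) multivariate time series
#'
#' Observations of `D` continuous features at strictly increasing,
#' non-negative times (hours since ICU admission). Every stored row is fully
#' observed: irregularity is modelled as completely missing time steps, not
#' per-feature gaps.
#'
#' @slot patientId character scalar identifier.
#' @slot times numeric vector of observation times in hours, strictly
#'   increasing and non-negative.
#' @slot values numeric matrix with one row per time and one column per
#'   feature; column names are feature names.
#' @export
setClass("PatientSeries",
  representation(patientId = "character", times = "numeric", values = "matrix"))

setValidity("PatientSeries", function(object) {
  msg <- character()
  if (length(object@patientId) != 1L) msg <- c(msg, "patientId must be a single string")
  t <- object@times
  if (length(t) != nrow(object@values))
    msg <- c(msg, "number of times must equal number of value rows")
  if (length(t) && any(t < 0)) msg <- c(msg, "times must be non-negative")
  if (length(t) > 1L && any(diff(t) <= 0)) msg <- c(msg, "times must be strictly increasing")
  if (ncol(object@values) < 1L) msg <- c(msg, "series must have at least one feature")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be fully observed and finite")
  if (length(msg)) msg else TRUE
})

#' A fully observed series on a regular time grid
#'
#' A [PatientSeries] whose times form a complete grid (no absent steps); the
#' carry-forward and continuous resampling paths both produce this class.
#'
#' @export
setClass("RegularSeries", contains = "PatientSeries")

#' A labelled cohort of patient time series
#'
#' Holds one [PatientSeries] per patient, a binary outcome label per patient
#' (1 = in-hospital death), optional split tags (`"train"`, `"val"`, `"test"`
#' or `"fold<k>"`), and a metadata list (e.g. generator settings for synthetic
#' cohorts).
#'
#' @slot series list of [PatientSeries], one per patient.
#' @slot labels integer vector of 0/1 outcomes, aligned with `series`.
#' @slot splits character vector of split tags (may be empty before
#'   [splitCohort()] is applied).
#' @slot metadata list of provenance information.
#' @export
setClass("PatientCohort",
  representation(series = "list", labels = "integer",
                 splits = "character", metadata = "list"))

setValidity("PatientCohort", function(object) {
  msg <- character()
  n <- length(object@series)
  if (!all(vapply(object@series, is, logical(1), "PatientSeries")))
    msg <- c(msg, "series must all be PatientSeries objects")
  if (length(object@labels) != n) msg <- c(msg, "labels must align one-to-one with series")
  if (n && !all(object@labels %in% c(0L, 1L))) msg <- c(msg, "labels must be 0/1")
  if (length(object@splits) && length(object@splits) != n)
    msg <- c(msg, "splits, when present, must align with series")
  if (n) {
    d <- vapply(object@series, function(s) ncol(s@values), integer(1))
    if (length(unique(d)) != 1L) msg <- c(msg, "all series must share the same feature count")
  }
  if (length(msg)) msg else TRUE
})

#' Monte Carlo dropout predictions for one evaluation split
#'
#' Per patient: `S` stochastic forward-pass probabilities, their mean (the
#' prediction) and variance (the predictive uncertainty), plus the true label.
#'
#' @slot patientId character vector.
#' @slot samples numeric matrix, patients x S draws.
#' @slot mean numeric vector of per-patient mean probabilities.
#' @slot variance numeric vector of per-patient sample variances (ML form,
#'   i.e. divided by S).
#' @slot labels integer 0/1 outcomes.
#' @export
setClass("PredictionSet",
  representation(patientId = "character", samples = "matrix",
                 mean = "numeric", variance = "numeric", labels = "integer"))

setValidity("PredictionSet", function(object) {
  msg <- character()
  n <- nrow(object@samples)
  if (ncol(object@samples) < 1L) msg <- c(msg, "need at least one sample draw")
  if (length(object@mean) != n || length(object@variance) != n ||
      length(object@labels) != n || length(object@patientId) != n)
    msg <- c(msg, "per-patient slots must align")
  if (any(object@variance < -1e-12)) msg <- c(msg, "variance must be non-negative")
  if (n && max(abs(object@mean - rowMeans(object@samples))) > 1e-8)
    msg <- c(msg, "mean must equal the average of the samples")
  if (length(msg)) msg else TRUE
})

#' Analytic per-layer FLOP counts for one encoder forward pass
#'
#' @slot counts data.frame with columns `component` and `flops`, itemising one
#'   forward pass on one patient.
#' @slot total numeric, sum of the component counts.
#' @slot stored numeric, stored attention-matrix entries (space audit).
#' @slot config list echoing the configuration the counts refer to.
#' @export
setClass("FlopsReport",
  representation(counts = "data.frame", total = "numeric",
                 stored = "numeric", config = "list"))

setValidity("FlopsReport", function(object) {
  msg <- character()
  if (any(object@counts$flops < 0)) msg <- c(msg, "counts must be non-negative")
  if (abs(object@total - sum(object@counts$flops)) > 1e-6)
    msg <- c(msg, "total must equal the sum of component counts")
  if (length(msg)) msg else TRUE
})

## ---- show methods ----------------------------------------------------------

setMethod("show", "PatientSeries", function(object) {
  cat(sprintf("%s '%s': %d time steps x %d features, t in [%g, %g] h\n",
              class(object), object@patientId, length(object@times),
              ncol(object@values),
              if (length(object@times)) min(object@times) else NA,
              if (length(object@times)) max(object@times) else NA))
})

setMethod("show", "PatientCohort", function(object) {
  n <- length(object@series)
  cat(sprintf("PatientCohort: %d patients, %d features, prevalence %.3f\n",
              n, if (n) ncol(object@series[[1]]@values) else 0L,
              if (n) mean(object@labels) else NA_real_))
  if (length(object@splits))
    print(table(split = object@splits))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet: %d patients x %d MC draws; mean uncertainty %.4g\n",
              nrow(object@samples), ncol(object@samples), mean(object@variance)))
})

setMethod("show", "FlopsReport", function(object) {
  cat(sprintf("FlopsReport (%s): total %.4g flops\n",
              object@config$kind, object@total))
  print(object@counts, row.names = FALSE)
})
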