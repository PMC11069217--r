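#' Accessors for PatientSeries and PatientCohort
#'
#' Slot access goes through these functions rather than `@`.
#'
#' @param x a [PatientSeries] or [PatientCohort].
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("seriesTimes", function(x) standardGeneric("seriesTimes"))

#' @rdname accessors
#' @export
setMethod("seriesTimes", "PatientSeries", function(x) x@times)

#' @rdname accessors
#' @export
setGeneric("seriesValues", function(x) standardGeneric("seriesValues"))

#' @rdname accessors
#' @export
setMethod("seriesValues", "PatientSeries", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname accessors
#' @export
setMethod("patientId", "PatientSeries", function(x) x@patientId)

#' @rdname accessors
#' @export
setGeneric("patientIds", function(x) standardGeneric("patientIds"))

#' @rdname accessors
#' @export
setMethod("patientIds", "PatientCohort",
          function(x) vapply(x@series, patientId, character(1)))

#' @rdname accessors
#' @export
setGeneric("cohortSeries", function(x) standardGeneric("cohortSeries"))

#' @rdname accessors
#' @export
setMethod("cohortSeries", "PatientCohort", function(x) x@series)

#' @rdname accessors
#' @export
setGeneric("cohortLabels", function(x) standardGeneric("cohortLabels"))

#' @rdname accessors
#' @export
setMethod("cohortLabels", "PatientCohort", function(x) x@labels)

#' @rdname accessors
#' @export
setGeneric("cohortSplits", function(x) standardGeneric("cohortSplits"))

#' @rdname accessors
#' @export
setMethod("cohortSplits", "PatientCohort", function(x) x@splits)

#' @rdname accessors
#' @export
setGeneric("cohortMetadata", function(x) standardGeneric("cohortMetadata"))

#' @rdname accessors
#' @export
setMethod("cohortMetadata", "PatientCohort", function(x) x@metadata)

#' @rdname accessors
#' @export
setGeneric("nPatients", function(x) standardGeneric("nPatients"))

#' @rdname accessors
#' @export
setMethod("nPatients", "PatientCohort", function(x) length(x@series))

#' Number of features shared by all series in a cohort
#' @param x a [PatientCohort].
#' @export
nFeatures <- function(x) {
  stopifnot(is(x, "PatientCohort"), nPatients(x) > 0L)
  ncol(x@series[[1L]]@values)
}

#' Restrict a cohort to one split tag
#'
#' @param x a [PatientCohort] with split tags assigned.
#' @param split one of the tags present in `cohortSplits(x)`.
#' @return A [PatientCohort] containing only the tagged patients.
#' @export
subsetSplit <- function(x, split) {
  stopifnot(is(x, "PatientCohort"))
  if (!length(x@splits)) stop("cohort has no split tags; run splitCohort() first")
  keep <- x@splits == split
  if (!any(keep)) stop("no patients carry split tag '", split, "'")
  new("PatientCohort", series = x@series[keep], labels = x@labels[keep],
      splits = x@splits[keep], metadata = x@metadata)
}

#' Keep an explicit subset of patients
#' @param x a [PatientCohort]; @param idx integer or logical index.
#' @export
subsetPatients <- function(x, idx) {
  stopifnot(is(x, "PatientCohort"))
  new("PatientCohort", series = x@series[idx], labels = x@labels[idx],
      splits = if (length(x@splits)) x@splits[idx] else character(),
      metadata = x@metadata)
}
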