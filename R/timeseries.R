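#' Hourly time grid
#'
#' The default observation grid covers the first 48 hours of an ICU stay at
#' hourly resolution: times `0, 1, ..., T-1`.
#'
#' @param T grid length (default 48).
#' @param dt spacing in hours (default 1).
#' @return Numeric vector of strictly increasing, non-negative times.
#' @export
timeGrid <- function(T = 48L, dt = 1) {
  stopifnot(T >= 1L, dt > 0)
  seq(0, by = dt, length.out = T)
}

checkGrid <- function(times) {
  if (!is.numeric(times) || !length(times)) stop("time grid must be a non-empty numeric vector")
  if (any(times < 0)) stop("time grid must be non-negative")
  if (length(times) > 1L && any(diff(times) <= 0)) stop("time grid must be strictly increasing")
  invisible(times)
}

#' Construct a PatientSeries
#'
#' @param patientId character identifier.
#' @param times numeric observation times (hours).
#' @param values numeric matrix, one row per time, one column per feature.
#' @return A [PatientSeries].
#' @export
patientSeries <- function(patientId, times, values) {
  if (is.vector(values)) values <- matrix(values, nrow = length(times))
  new("PatientSeries", patientId = as.character(patientId),
      times = as.numeric(times), values = values)
}

#' Construct a PatientCohort
#'
#' @param series list of [PatientSeries].
#' @param labels binary 0/1 outcome per patient.
#' @param splits optional split tags.
#' @param metadata optional provenance list.
#' @export
patientCohort <- function(series, labels, splits = character(), metadata = list()) {
  new("PatientCohort", series = series, labels = as.integer(labels),
      splits = as.character(splits), metadata = metadata)
}

#' Induce irregularity by removing whole time steps
#'
#' Removes `round(rate * t_d)` of a series' `t_d` time steps uniformly at
#' random without replacement. The first time step is always retained so that
#' downstream carry-forward imputation and the ODE initial state remain
#' defined; removal candidates are therefore steps `2..t_d`.
#'
#' @param series a [PatientSeries] with at least 2 time steps.
#' @param rate fraction of steps to remove, in `[0, 1)`.
#' @param seed integer seed; the same `(series, rate, seed)` always yields the
#'   same retained set.
#' @return A [PatientSeries] on the retained times.
#' @export
dropTimeSteps <- function(series, rate, seed) {
  stopifnot(is(series, "PatientSeries"))
  if (!is.numeric(rate) || length(rate) != 1L || rate < 0 || rate >= 1)
    stop("rate must be a single number in [0, 1)")
  td <- length(series@times)
  if (td < 2L) stop("series must have at least 2 time steps")
  nDrop <- round(rate * td)
  if (nDrop == 0L) return(series)
  if (nDrop > td - 1L)
    stop("rate removes every step after the always-retained first one")
  cand <- 2:td
  drop <- withSeed(deriveSeed(seed, paste0("drop:", series@patientId)),
                   cand[sample.int(length(cand), nDrop)])
  keep <- setdiff(seq_len(td), drop)
  patientSeries(series@patientId, series@times[keep],
                series@values[keep, , drop = FALSE])
}

#' Carry-forward imputation onto a regular grid
#'
#' At each grid time the value is the most recent observed row at or before
#' that time; observed grid times reproduce their rows exactly.
#'
#' @param series a [PatientSeries].
#' @param grid numeric target grid (default the hourly 48-step grid).
#' @return A [RegularSeries] on `grid`.
#' @export
carryForwardFill <- function(series, grid = timeGrid(48L)) {
  stopifnot(is(series, "PatientSeries"))
  checkGrid(grid)
  if (grid[1L] < series@times[1L] - 1e-9)
    stop("missing anchor: grid starts before the first observation")
  idx <- findInterval(grid + 1e-9, series@times)
  vals <- series@values[idx, , drop = FALSE]
  rownames(vals) <- NULL
  new("RegularSeries", patientId = series@patientId,
      times = as.numeric(grid), values = vals)
}

#' Write a cohort as long-format CSV files
#'
#' Writes `cohort.csv` (columns `patient_id,time_h,feature,value`) and
#' `labels.csv` (columns `patient_id,label` plus `split` when tags are
#' present) into `path`. Values round-trip at full double precision.
#'
#' @param cohort a [PatientCohort].
#' @param path output directory (created if absent).
#' @return Invisibly, the two file paths.
#' @export
writeCohort <- function(cohort, path) {
  stopifnot(is(cohort, "PatientCohort"))
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  ids <- patientIds(cohort)
  long <- data.table::rbindlist(lapply(seq_along(cohort@series), function(i) {
    s <- cohort@series[[i]]
    D <- ncol(s@values)
    feats <- colnames(s@values)
    if (is.null(feats)) feats <- paste0("f", seq_len(D))
    ## numerics rendered at 17 significant digits so doubles round-trip
    ## bit-exactly through the text format
    data.table::data.table(
      patient_id = s@patientId,
      time_h = sprintf("%.17g", rep(s@times, times = D)),
      feature = rep(feats, each = length(s@times)),
      value = sprintf("%.17g", as.vector(s@values)))
  }))
  lab <- data.table::data.table(patient_id = ids, label = cohort@labels)
  if (length(cohort@splits)) lab$split <- cohort@splits
  fCohort <- file.path(path, "cohort.csv")
  fLabels <- file.path(path, "labels.csv")
  data.table::fwrite(long, fCohort)
  data.table::fwrite(lab, fLabels)
  invisible(c(cohort = fCohort, labels = fLabels))
}

#' Read a cohort from long-format CSV files
#'
#' Inverse of [writeCohort()]: expects `cohort.csv` and `labels.csv` under
#' `path` (or explicit file paths). Every patient must carry the same feature
#' set at every recorded time, duplicate `(patient, time, feature)` records
#' are rejected, and every patient must appear in the label table.
#'
#' @param path directory containing the two CSV files.
#' @param cohortFile,labelsFile optional explicit file paths.
#' @return A [PatientCohort].
#' @export
readCohort <- function(path,
                       cohortFile = file.path(path, "cohort.csv"),
                       labelsFile = file.path(path, "labels.csv")) {
  if (!file.exists(cohortFile)) stop("cohort file not found: ", cohortFile)
  if (!file.exists(labelsFile)) stop("labels file not found: ", labelsFile)
  long <- data.table::fread(cohortFile,
                            colClasses = list(character = "patient_id"))
  if (!nrow(long)) stop("empty cohort file: ", cohortFile)
  need <- c("patient_id", "time_h", "feature", "value")
  if (!all(need %in% names(long)))
    stop("cohort file must have columns ", paste(need, collapse = ", "))
  if (anyDuplicated(long[, c("patient_id", "time_h", "feature")]))
    stop("duplicate (patient, time, feature) records")
  feats <- unique(long$feature)
  lab <- data.table::fread(labelsFile,
                           colClasses = list(character = "patient_id"))
  if (!nrow(lab)) stop("empty labels file: ", labelsFile)
  ids <- unique(long$patient_id)
  missingLab <- setdiff(ids, lab$patient_id)
  if (length(missingLab))
    stop("label table missing patients: ", paste(head(missingLab, 5), collapse = ", "))
  patient_id <- time_h <- NULL # NSE note for data.table
  series <- lapply(ids, function(id) {
    sub <- long[patient_id == id]
    wide <- data.table::dcast(sub, time_h ~ feature, value.var = "value")
    if (anyNA(wide))
      stop("inconsistent feature set for patient ", id,
           ": every recorded time must carry all features")
    wide <- wide[order(time_h)]
    vals <- as.matrix(wide[, feats, with = FALSE])
    rownames(vals) <- NULL
    patientSeries(id, wide$time_h, vals)
  })
  lab <- lab[match(ids, lab$patient_id), ]
  patientCohort(series, lab$label,
                splits = if ("split" %in% names(lab)) lab$split else character())
}

#' Assign train/validation/test splits
#'
#' Two schemes are supported. `holdout`: a fraction of patients is tagged
#' `test`, and the validation set is carved as 20% of the remaining training
#' portion. `kfold`: patients are partitioned into `k` folds (tags
#' `fold1..foldk`); materialise one fold with [foldSplit()], which again
#' carves 20% of that fold's training portion as validation.
#'
#' @param cohort a [PatientCohort].
#' @param scheme list, either `list(type = "holdout", test = 0.2)` or
#'   `list(type = "kfold", k = 5)`.
#' @param seed integer seed; folds are deterministic given the seed.
#' @param valFraction validation share of the training portion (default 0.2).
#' @return The cohort with split tags filled in.
#' @export
splitCohort <- function(cohort, scheme = list(type = "holdout", test = 0.2),
                        seed = 1L, valFraction = 0.2) {
  stopifnot(is(cohort, "PatientCohort"))
  n <- nPatients(cohort)
  perm <- withSeed(deriveSeed(seed, "split"), sample.int(n))
  tags <- character(n)
  if (identical(scheme$type, "holdout")) {
    nTest <- round(scheme$test * n)
    test <- perm[seq_len(nTest)]
    rest <- perm[-seq_len(nTest)]
    nVal <- round(valFraction * length(rest))
    val <- rest[seq_len(nVal)]
    tags[test] <- "test"; tags[val] <- "val"
    tags[setdiff(rest, val)] <- "train"
  } else if (identical(scheme$type, "kfold")) {
    k <- scheme$k
    if (k > n) stop("k-fold split requires n >= k")
    fold <- rep(seq_len(k), length.out = n)
    tags[perm] <- paste0("fold", fold)
  } else stop("unknown split scheme type: ", scheme$type)
  cohort@splits <- tags
  validObject(cohort)
  cohort
}

#' Materialise one cross-validation fold
#'
#' @param cohort a k-fold tagged [PatientCohort].
#' @param fold integer fold to use as the test set.
#' @param seed seed for carving the validation subset.
#' @param valFraction validation share of the fold's training portion.
#' @return The cohort re-tagged `train`/`val`/`test`.
#' @export
foldSplit <- function(cohort, fold, seed = 1L, valFraction = 0.2) {
  stopifnot(is(cohort, "PatientCohort"), length(cohort@splits) > 0L)
  if (!any(grepl("^fold", cohort@splits))) stop("cohort is not k-fold tagged")
  tags <- character(nPatients(cohort))
  isTest <- cohort@splits == paste0("fold", fold)
  if (!any(isTest)) stop("no patients in fold ", fold)
  tags[isTest] <- "test"
  rest <- which(!isTest)
  perm <- withSeed(deriveSeed(seed, paste0("fold-val:", fold)),
                   sample(rest))
  nVal <- round(valFraction * length(rest))
  tags[perm[seq_len(nVal)]] <- "val"
  tags[perm[-seq_len(nVal)]] <- "train"
  cohort@splits <- tags
  cohort
}
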