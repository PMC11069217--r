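test_that("dropTimeSteps removes the exact count, keeps the first step, and is seeded", {
  for (T in c(2:10, 24, 48, 97, 100)) {
    s <- patientSeries("p1", 0:(T - 1), matrix(seq_len(T), ncol = 1))
    for (rate in c(0, 0.25, 0.5, 0.75)) {
      nDrop <- round(rate * T)
      if (nDrop > T - 1) next
      out <- dropTimeSteps(s, rate, seed = 11L)
      expect_equal(length(seriesTimes(out)), T - nDrop)
      expect_equal(seriesTimes(out)[1], 0)
      expect_true(all(diff(seriesTimes(out)) > 0))
      out2 <- dropTimeSteps(s, rate, seed = 11L)
      expect_identical(seriesTimes(out), seriesTimes(out2))
      ## retained rows carry their original values
      expect_equal(as.numeric(seriesValues(out)[, 1]), seriesTimes(out) + 1)
    }
  }
})

test_that("dropTimeSteps identity at rate 0 and argument validation", {
  s <- patientSeries("p1", 0:9, matrix(rnorm(20), 10, 2))
  expect_identical(dropTimeSteps(s, 0, 1L), s)
  expect_error(dropTimeSteps(s, 1, 1L), "rate")
  expect_error(dropTimeSteps(s, -0.1, 1L), "rate")
  one <- patientSeries("p1", 0, matrix(1, 1, 1))
  expect_error(dropTimeSteps(one, 0.5, 1L), "at least 2")
})

test_that("carryForwardFill is piecewise-constant and exact at observed times", {
  s <- patientSeries("p", c(0, 2), matrix(c(1, 3, 2, 4), 2, 2))
  out <- carryForwardFill(s, 0:3)
  expect_equal(unname(seriesValues(out)),
               matrix(c(1, 1, 3, 3, 2, 2, 4, 4), 4, 2))
  ## fully observed series is reproduced exactly
  full <- patientSeries("p", 0:4, matrix(rnorm(10), 5, 2))
  expect_identical(unname(seriesValues(carryForwardFill(full, 0:4))),
                   unname(seriesValues(full)))
  ## a single anchor fills the whole grid
  single <- patientSeries("p", 0, matrix(5, 1, 1))
  filled <- carryForwardFill(single, 0:47)
  expect_equal(unname(seriesValues(filled)), matrix(5, 48, 1))
  expect_s4_class(filled, "RegularSeries")
  expect_error(carryForwardFill(patientSeries("p", 2, matrix(1)), 0:3),
               "anchor")
})

test_that("carry-forward restricted to observed times is bit-exact after dropping", {
  s <- patientSeries("p", 0:19, matrix(rnorm(60), 20, 3))
  thin <- dropTimeSteps(s, 0.5, seed = 3L)
  filled <- carryForwardFill(thin, 0:19)
  obs <- match(seriesTimes(thin), seriesTimes(filled))
  expect_identical(seriesValues(filled)[obs, ], seriesValues(thin)[, ])
})

test_that("cohort CSV round-trip is lossless", {
  dir <- withr::local_tempdir()
  coh <- randomCohort(1)
  writeCohort(coh, dir)
  expectCohortEqual(readCohort(dir), coh)
  for (seed in 2:100) {
    coh <- randomCohort(seed)
    writeCohort(coh, dir)
    expectCohortEqual(readCohort(dir), coh)
  }
})

test_that("cohort reader rejects malformed inputs", {
  dir <- withr::local_tempdir()
  coh <- randomCohort(5)
  writeCohort(coh, dir)
  ## label table missing a patient
  lab <- as.data.frame(data.table::fread(file.path(dir, "labels.csv")))
  data.table::fwrite(lab[-1, , drop = FALSE], file.path(dir, "labels.csv"))
  expect_error(readCohort(dir), "missing patients")
  data.table::fwrite(lab, file.path(dir, "labels.csv"))
  ## duplicate (patient, time, feature) record
  long <- as.data.frame(data.table::fread(file.path(dir, "cohort.csv")))
  data.table::fwrite(rbind(long, long[1, ]), file.path(dir, "cohort.csv"))
  expect_error(readCohort(dir), "duplicate")
  ## inconsistent feature sets (only possible with > 1 feature)
  if (length(unique(long$feature)) > 1L) {
    data.table::fwrite(long[-1, , drop = FALSE], file.path(dir, "cohort.csv"))
    expect_error(readCohort(dir), "all features")
  }
  ## empty file
  data.table::fwrite(long[0, , drop = FALSE], file.path(dir, "cohort.csv"))
  expect_error(readCohort(dir), "empty")
})

test_that("splitCohort partitions patients deterministically", {
  coh <- generateCohort(cohortSpec(n = 100, T = 4, D = 2, seed = 1))
  hold <- splitCohort(coh, list(type = "holdout", test = 0.2), seed = 9)
  tab <- table(cohortSplits(hold))
  expect_equal(unname(tab["test"]), 20)
  expect_equal(unname(tab["val"]), 16) # 20% of the remaining 80
  expect_equal(unname(tab["train"]), 64)
  hold2 <- splitCohort(coh, list(type = "holdout", test = 0.2), seed = 9)
  expect_identical(cohortSplits(hold), cohortSplits(hold2))

  small <- generateCohort(cohortSpec(n = 10, T = 4, D = 2, seed = 2))
  kf <- splitCohort(small, list(type = "kfold", k = 5), seed = 1)
  expect_equal(as.vector(table(cohortSplits(kf))), rep(2L, 5))
  f1 <- foldSplit(kf, 1, seed = 1)
  expect_setequal(unique(cohortSplits(f1)), c("train", "val", "test"))
  expect_equal(sum(cohortSplits(f1) == "test"), 2)
  expect_error(splitCohort(small, list(type = "kfold", k = 11), seed = 1),
               "n >= k")
})

test_that("series and cohort validity invariants are enforced", {
  expect_error(patientSeries("p", c(0, 0), matrix(1:4, 2, 2)), "increasing")
  expect_error(patientSeries("p", c(-1, 0), matrix(1:4, 2, 2)), "non-negative")
  expect_error(patientSeries("p", 0:1, matrix(c(1, NA, 3, 4), 2, 2)), "observed")
  s <- patientSeries("p", 0:1, matrix(1:4, 2, 2))
  expect_error(patientCohort(list(s), labels = c(1L, 0L)), "align")
  expect_error(patientCohort(list(s), labels = 2L), "0/1")
})
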