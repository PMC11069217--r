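## Training-behaviour tests run on small cohorts (T = 8..16, n <= 120) so the
## suite stays fast; full-scale study conditions live in test-acceptance.R.

tinyModelCfg <- function(kind, seed = 1L, T = 12L, ...) {
  modelConfig(kind = kind, e = 6L,
              attention = tinyAttnCfg(l = 4L),
              embedHidden = 8L, fieldHidden = c(12L, 12L),
              fieldDropout = 0, seed = seed, ...)
}

test_that("every model kind emits probabilities and trains with decreasing loss", {
  coh <- tinyCohort(n = 48L, T = 12L, D = 4L, seed = 7)
  for (kind in c("perceiver", "transformer", "coper", "ctransformer", "lstm_cf")) {
    model <- buildModel(tinyModelCfg(kind), 12L, 4L)
    p <- predictProb(model, coh)
    expect_length(p, 48L)
    expect_true(all(p > 0 & p < 1))
    fit <- trainModel(model, coh,
                      trainConfig(lr = 1e-3, batchSize = 16L, maxEpochs = 5L,
                                  seed = 3L))
    expect_lt(fit$history$trainLoss[5], fit$history$trainLoss[1])
  }
})

test_that("perceiver and transformer parameter counts differ only by the latent bank", {
  T <- 10L; D <- 4L
  acfg <- attentionConfig(e = 6L, dk = 8L, l = T, latentDim = 6L, dropout = 0)
  pv <- buildModel(modelConfig(kind = "perceiver", e = 6L, attention = acfg), T, D)
  tf <- buildModel(modelConfig(kind = "transformer", e = 6L, attention = acfg), T, D)
  expect_equal(countParams(pv) - countParams(tf), T * 6L)
})

test_that("the LSTM baseline is two layers with hidden state 50", {
  model <- buildModel(modelConfig(kind = "lstm_cf"), 8L, 4L)
  expect_equal(dim(model$params$l1$U), c(50L, 200L))
  expect_equal(dim(model$params$l2$U), c(50L, 200L))
  expect_equal(dim(model$params$l2$W), c(50L, 200L))
})

test_that("early stopping halts after patience epochs without improvement", {
  ## validation labels are flipped relative to train, so validation loss
  ## worsens from the first epoch onwards
  coh <- tinyCohort(n = 60L, T = 8L, D = 3L, noiseSd = 0.1, seed = 11)
  flip <- cohortLabels(coh)
  flip[cohortSplits(coh) == "val"] <- 1L - flip[cohortSplits(coh) == "val"]
  coh2 <- patientCohort(cohortSeries(coh), flip, cohortSplits(coh))
  model <- buildModel(tinyModelCfg("lstm_cf", T = 8L), 8L, 3L)
  fit <- trainModel(model, coh2,
                    trainConfig(lr = 5e-3, batchSize = 16L, maxEpochs = 50L,
                                patience = 10L, seed = 2L))
  expect_equal(nrow(fit$history), 1L + 10L)
  expect_equal(fit$bestEpoch, 1L)
})

test_that("training is deterministic given the seed", {
  coh <- tinyCohort(n = 40L, T = 8L, D = 3L, seed = 5)
  run <- function() {
    m <- buildModel(tinyModelCfg("coper", seed = 4L, T = 8L), 8L, 3L)
    m <- trainModel(m, coh, trainConfig(batchSize = 16L, maxEpochs = 3L,
                                        seed = 9L))
    evaluateModel(m, coh)
  }
  e1 <- run(); e2 <- run()
  expect_identical(e1, e2)
})

test_that("a separable cohort is learned to high training AUROC", {
  coh <- tinyCohort(n = 120L, T = 16L, D = 4L, noiseSd = 0.25, seed = 13)
  model <- buildModel(modelConfig(kind = "perceiver", e = 16L,
                                  attention = attentionConfig(e = 16L, dk = 16L,
                                                              dropout = 0.5),
                                  seed = 1L), 16L, 4L)
  fit <- trainModel(model, coh, trainConfig(batchSize = 32L, maxEpochs = 30L,
                                            seed = 1L))
  tr <- subsetSplit(coh, "train")
  auc <- computeAUROC(predictProb(fit, tr), cohortLabels(tr))
  expect_gte(auc, 0.9)
})

test_that("degenerate splits and single-class data are rejected", {
  coh <- tinyCohort(n = 20L, T = 8L, D = 3L, seed = 6)
  noSplit <- patientCohort(cohortSeries(coh), cohortLabels(coh))
  model <- buildModel(tinyModelCfg("lstm_cf", T = 8L), 8L, 3L)
  expect_error(trainModel(model, noSplit), "split")
  oneClass <- patientCohort(cohortSeries(coh), rep(0L, 20L), cohortSplits(coh))
  expect_error(trainModel(model, oneClass), "single class")
  expect_error(evaluateModel(model, oneClass), "single class")
})

test_that("ranking metrics behave at their boundary cases", {
  y <- c(1, 0, 1, 0, 1)
  expect_equal(computeAUROC(y, y), 1.0)
  expect_equal(computeAUPRC(y, y), 1.0)
  expect_equal(computeAUROC(rep(0.3, 5), y), 0.5)
  expect_error(computeAUROC(1:3, c(1, 1, 1)), "single class")
  ## random scores: AUPRC baseline equals prevalence
  set.seed(8)
  yy <- rbinom(1000, 1, 0.3)
  sc <- runif(1000)
  expect_lt(abs(computeAUPRC(sc, yy) - 0.3), 0.05)
  expect_lt(abs(computeAUROC(sc, yy) - 0.5), 0.05)
})

test_that("computeAUROC agrees with the pROC reference", {
  skip_if_not_installed("pROC")
  set.seed(10)
  for (i in 1:5) {
    y <- rbinom(60, 1, 0.4)
    if (length(unique(y)) < 2) next
    s <- rnorm(60) + y
    ref <- suppressMessages(as.numeric(pROC::auc(y, s)))
    expect_equal(computeAUROC(s, y), ref, tolerance = 1e-10)
  }
})

test_that("the irregularity experiment emits the full grid with shared missingness", {
  coh <- tinyCohort(n = 40L, T = 8L, D = 3L, seed = 15)
  res <- irregularityExperiment(
    coh, kinds = "lstm_cf", rates = c(0, 0.25), seeds = 1:2,
    tcfg = trainConfig(batchSize = 16L, maxEpochs = 2L),
    cfgFor = function(kind, seed) tinyModelCfg(kind, seed = seed, T = 8L))
  expect_equal(nrow(res), 1L * 2L * 2L)
  expect_setequal(unique(res$rate), c(0, 0.25))
  expect_true(all(res$auroc >= 0 & res$auroc <= 1))
})
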