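## Shared fixtures and independent oracles, all built in code at test time.

## Small labelled cohort with train/val/test tags.
tinyCohort <- function(n = 60L, T = 12L, D = 4L, noiseSd = 0.25,
                       missingRate = 0, seed = 7L, prevalence = 0.4) {
  coh <- generateCohort(cohortSpec(n = n, T = T, D = D, noiseSd = noiseSd,
                                   missingRate = missingRate,
                                   prevalence = prevalence, seed = seed))
  splitCohort(coh, seed = seed)
}

tinyAttnCfg <- function(e = 6L, l = 4L, ...) {
  attentionConfig(e = e, dk = 8L, nHeads = 1L, l = l, dropout = 0, ...)
}

## Independent brute-force evaluation of scaled dot-product attention:
## explicit loops, no shared code with the implementation.
bruteAttention <- function(Q, K, V) {
  q <- nrow(Q); k <- nrow(K); dk <- ncol(K)
  out <- matrix(0, q, ncol(V))
  W <- matrix(0, q, k)
  for (i in seq_len(q)) {
    s <- numeric(k)
    for (j in seq_len(k)) s[j] <- sum(Q[i, ] * K[j, ]) / sqrt(dk)
    e <- exp(s - max(s))
    w <- e / sum(e)
    W[i, ] <- w
    for (j in seq_len(k)) out[i, ] <- out[i, ] + w[j] * V[j, ]
  }
  list(output = out, weights = W)
}

## Brute-force AUROC over all label pairs (independent of computeAUROC).
pairwiseAUROC <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

## Random small cohort with irregular times for round-trip tests.
randomCohort <- function(seed) {
  set.seed(seed)
  n <- sample(2:5, 1)
  D <- sample(1:4, 1)
  series <- lapply(seq_len(n), function(i) {
    td <- sample(2:7, 1)
    times <- sort(sample(0:30, td)) + runif(td, 0, 0.4)
    vals <- matrix(rnorm(td * D) * 10^sample(-3:3, 1), td, D)
    colnames(vals) <- paste0("feat_", seq_len(D))
    patientSeries(paste0("pt", i), times, vals)
  })
  patientCohort(series, labels = rbinom(n, 1, 0.5))
}

expectCohortEqual <- function(a, b) {
  expect_equal(patientIds(a), patientIds(b))
  expect_equal(cohortLabels(a), cohortLabels(b))
  for (i in seq_len(nPatients(a))) {
    expect_identical(seriesTimes(cohortSeries(a)[[i]]),
                     seriesTimes(cohortSeries(b)[[i]]))
    expect_identical(unname(seriesValues(cohortSeries(a)[[i]])),
                     unname(seriesValues(cohortSeries(b)[[i]])))
  }
}
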