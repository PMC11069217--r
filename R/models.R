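#' Model configuration
#'
#' Five model kinds are supported. `"coper"` embeds the irregular series,
#' learns patient-state dynamics with a neural ODE, resamples a regular
#' series and encodes it with the Perceiver; `"ctransformer"` is the same
#' with the transformer encoder. `"perceiver"` and `"transformer"` consume
#' carry-forward-filled regular series directly (after embedding), and
#' `"lstm_cf"` is the 2-layer LSTM baseline on carry-forward-filled input.
#'
#' @param kind one of `"perceiver"`, `"transformer"`, `"coper"`,
#'   `"ctransformer"`, `"lstm_cf"`.
#' @param e embedding width (default 32).
#' @param attention an [attentionConfig()]; defaults to the study settings
#'   with `e = e`.
#' @param embedHidden hidden width of the row-wise embedding MLP.
#' @param fieldHidden hidden widths of the derivative-field MLP.
#' @param fieldDropout dropout rate inside the derivative field.
#' @param stepsPerInterval RK4 sub-steps between grid times.
#' @param resampleMode `"auto"`, `"full"` or `"fill"`; `auto` resolves to
#'   `fill` at >= 50% missingness and `full` below.
#' @param lstmHidden,lstmLayers LSTM baseline size (defaults 50 and 2).
#' @param seed integer seed for parameter initialisation.
#' @return A list of class `"modelConfig"`.
#' @export
modelConfig <- function(kind = c("perceiver", "transformer", "coper",
                                 "ctransformer", "lstm_cf"),
                        e = 32L, attention = NULL, embedHidden = 32L,
                        fieldHidden = c(128L, 128L, 128L), fieldDropout = 0.5,
                        stepsPerInterval = 1L,
                        resampleMode = c("auto", "full", "fill"),
                        lstmHidden = 50L, lstmLayers = 2L, seed = 1L) {
  kind <- match.arg(kind)
  resampleMode <- match.arg(resampleMode)
  if (is.null(attention)) attention <- attentionConfig(e = e)
  if (attention$e != e) stop("attention config width must equal e")
  if (lstmLayers != 2L) stop("the LSTM baseline is fixed at two layers")
  structure(list(kind = kind, e = as.integer(e), attention = attention,
                 embedHidden = as.integer(embedHidden),
                 fieldHidden = as.integer(fieldHidden),
                 fieldDropout = fieldDropout,
                 stepsPerInterval = as.integer(stepsPerInterval),
                 resampleMode = resampleMode,
                 lstmHidden = as.integer(lstmHidden),
                 seed = as.integer(seed)),
            class = "modelConfig")
}

#' Training configuration
#'
#' Defaults follow the study settings: Adam with a constant learning rate of
#' 1e-4, batch size 64, at most 100 epochs, early stopping on validation
#' loss with patience 10, dropout 0.5 (set in the model config).
#'
#' @param lr learning rate.
#' @param batchSize mini-batch size.
#' @param maxEpochs maximum number of epochs.
#' @param patience early-stopping patience (consecutive epochs without
#'   validation-loss improvement).
#' @param seed integer seed controlling batching and dropout draws.
#' @return A list of class `"trainConfig"`.
#' @export
trainConfig <- function(lr = 1e-4, batchSize = 64L, maxEpochs = 100L,
                        patience = 10L, seed = 1L) {
  stopifnot(lr > 0, batchSize >= 1L, maxEpochs >= 1L, patience >= 1L)
  structure(list(lr = lr, batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "trainConfig")
}

isContinuousKind <- function(kind) kind %in% c("coper", "ctransformer")

#' Build an untrained model
#'
#' @param cfg a [modelConfig()].
#' @param T grid length of the input schema.
#' @param D raw feature count.
#' @return A list of class `"cpsModel"` holding the seeded parameter trees.
#' @export
buildModel <- function(cfg, T, D) {
  stopifnot(inherits(cfg, "modelConfig"), T >= 2L, D >= 1L)
  acfg <- cfg$attention
  if (is.null(acfg$l)) acfg$l <- as.integer(T)
  params <- withSeed(deriveSeed(cfg$seed, "init"), {
    if (cfg$kind == "lstm_cf") {
      lstmInit(D, cfg$lstmHidden)
    } else {
      p <- list(embed = embedInit(D, cfg$e, cfg$embedHidden))
      if (isContinuousKind(cfg$kind)) {
        widths <- c(cfg$e + 1L, cfg$fieldHidden, cfg$e)
        p$field <- lapply(seq_len(length(widths) - 1L), function(i)
          list(W = initMat(widths[i], widths[i + 1L]),
               b = rep(0, widths[i + 1L])))
      }
      encKind <- if (cfg$kind %in% c("perceiver", "coper"))
        "perceiver" else "transformer"
      p$enc <- if (encKind == "perceiver") initPerceiverParams(acfg, T)
               else initTransformerParams(acfg, T)
      p$head <- headInit(if (encKind == "perceiver") acfg$latentDim else acfg$e)
      p
    }
  })
  structure(list(kind = cfg$kind, cfg = cfg, acfg = acfg,
                 T = as.integer(T), D = as.integer(D),
                 params = params, trained = FALSE, history = NULL),
            class = "cpsModel")
}

#' @export
print.cpsModel <- function(x, ...) {
  cat(sprintf("cpsModel kind='%s' (T=%d, D=%d, e=%d): %d parameters, %s\n",
              x$kind, x$T, x$D, x$cfg$e, countParams(x),
              if (x$trained) "trained" else "untrained"))
  invisible(x)
}

#' Total number of learnable parameters
#' @param model a `cpsModel`.
#' @export
countParams <- function(model) {
  n <- 0
  treeMap(function(x) { n <<- n + length(x); x }, model$params)
  as.integer(n)
}

## Resolve the resampling mode for a given missingness rate.
resolveMode <- function(cfg, rate = 0) {
  if (cfg$resampleMode != "auto") cfg$resampleMode
  else if (rate >= 0.5) "fill" else "full"
}

## ---- input preparation -----------------------------------------------------
## Continuous kinds keep the irregular series (values + grid-index map);
## regular kinds are carry-forward filled onto the model grid.

prepareInput <- function(model, cohort) {
  grid <- timeGrid(model$T)
  series <- cohortSeries(cohort)
  if (model$kind == "lstm_cf" || model$kind %in% c("perceiver", "transformer")) {
    X <- array(0, dim = c(length(series), model$T, model$D))
    for (i in seq_along(series))
      X[i, , ] <- seriesValues(carryForwardFill(series[[i]], grid))
    list(type = "regular", X = X, grid = grid)
  } else {
    vals <- lapply(series, seriesValues)
    obsRow <- matrix(NA_integer_, length(series), model$T)
    for (i in seq_along(series)) {
      gi <- round(seriesTimes(series[[i]])) + 1L
      if (any(gi < 1L | gi > model$T) ||
          max(abs(seriesTimes(series[[i]]) - grid[gi])) > 1e-6)
        stop("continuous kinds require observed times on the hourly grid")
      obsRow[i, gi] <- seq_along(gi)
    }
    list(type = "irregular", vals = vals, obsRow = obsRow, grid = grid)
  }
}

## ---- batched forward/backward ---------------------------------------------

batchFwd <- function(model, inputs, idx, train = FALSE, mode = "full") {
  p <- model$params
  acfg <- model$acfg
  if (model$kind == "lstm_cf") {
    X <- inputs$X[idx, , , drop = FALSE]
    fw <- lstmFwd(X, p, model$cfg$lstmHidden,
                  dropout = acfg$dropout, train = train)
    return(list(probs = fw$probs, lstm = fw))
  }
  encKind <- if (model$kind %in% c("perceiver", "coper"))
    "perceiver" else "transformer"
  B <- length(idx)
  if (inputs$type == "regular") {
    X <- inputs$X[idx, , , drop = FALSE]
    flat <- matrix(aperm(X, c(2, 1, 3)), B * model$T, model$D)
    emb <- embedFwd(flat, p$embed)
    Xe <- array(emb$out, dim = c(model$T, B, model$cfg$e))
    getX <- function(b) matrix(Xe[, b, ], model$T, model$cfg$e)
    rs <- NULL; masks <- NULL; Elist <- NULL
  } else {
    Elist0 <- lapply(inputs$vals[idx], identity)
    rows <- vapply(Elist0, nrow, integer(1))
    flat <- do.call(rbind, Elist0)
    emb <- embedFwd(flat, p$embed)
    Elist <- split.data.frame(emb$out, rep(seq_len(B), rows))
    Elist <- lapply(Elist, as.matrix)
    masks <- NULL
    if (train && model$cfg$fieldDropout > 0)
      masks <- lapply(model$cfg$fieldHidden, function(w)
        (matrix(runif(B * w), B, w) >= model$cfg$fieldDropout) /
          (1 - model$cfg$fieldDropout))
    rs <- resampleFwd(inputs$obsRow[idx, , drop = FALSE], Elist, p$field,
                      mode, scaledTimes = inputs$grid / model$T,
                      nsub = model$cfg$stepsPerInterval, masks = masks)
    getX <- function(b) matrix(rs$out[b, , ], model$T, model$cfg$e)
  }
  encCaches <- vector("list", B)
  headCaches <- vector("list", B)
  probs <- numeric(B)
  for (b in seq_len(B)) {
    enc <- encoderFwd(getX(b), p$enc, acfg, encKind, train)
    hd <- headFwd(enc$out, p$head)
    encCaches[[b]] <- enc
    headCaches[[b]] <- hd
    probs[b] <- hd$prob
  }
  list(probs = probs, emb = emb, rs = rs, masks = masks, Elist = Elist,
       encCaches = encCaches, headCaches = headCaches, B = B, idx = idx)
}

batchBwd <- function(model, inputs, fw, dz) {
  p <- model$params
  acfg <- model$acfg
  if (model$kind == "lstm_cf")
    return(lstmBwd(dz, fw$lstm, p, model$cfg$lstmHidden))
  B <- fw$B
  encKind <- if (model$kind %in% c("perceiver", "coper"))
    "perceiver" else "transformer"
  grads <- treeZero(p)
  dX <- array(0, dim = c(B, model$T, model$cfg$e))
  for (b in seq_len(B)) {
    hb <- headBwd(dz[b], fw$headCaches[[b]], p$head)
    grads$head <- treeMap(`+`, grads$head, hb$grads)
    eb <- encoderBwd(hb$dH, fw$encCaches[[b]], p$enc, acfg)
    grads$enc <- treeMap(`+`, grads$enc, eb$grads)
    dX[b, , ] <- eb$dX
  }
  if (inputs$type == "regular") {
    flatD <- matrix(aperm(dX, c(2, 1, 3)), B * model$T, model$cfg$e)
    ebk <- embedBwd(flatD, fw$emb, p$embed)
    grads$embed <- treeMap(`+`, grads$embed, ebk$grads)
  } else {
    acc <- new.env()
    acc$g <- treeZero(p$field)
    dE <- resampleBwd(dX, fw$rs, fw$Elist, p$field, fw$masks, acc)
    grads$field <- treeMap(`+`, grads$field, acc$g)
    flatD <- do.call(rbind, dE)
    ebk <- embedBwd(flatD, fw$emb, p$embed)
    grads$embed <- treeMap(`+`, grads$embed, ebk$grads)
  }
  grads
}

bceLoss <- function(probs, y) {
  pc <- pmin(pmax(probs, 1e-12), 1 - 1e-12)
  -mean(y * log(pc) + (1 - y) * log(1 - pc))
}

## ---- training --------------------------------------------------------------

#' Train a model on the cohort's train split, early-stopping on validation
#'
#' Minimises binary cross-entropy with Adam; stops when the validation loss
#' has not improved for `patience` consecutive epochs (or at `maxEpochs`)
#' and restores the best-validation parameters. Fully deterministic given
#' the training seed (batch order and all dropout draws flow from it).
#'
#' @param model a `cpsModel` from [buildModel()].
#' @param cohort a [PatientCohort] with `train` and `val` split tags.
#' @param tcfg a [trainConfig()].
#' @param rate missingness rate of the input (used only to resolve the
#'   `auto` resampling mode).
#' @param verbose print per-epoch losses.
#' @return The trained model; `$history` holds per-epoch train/val losses.
#' @export
trainModel <- function(model, cohort, tcfg = trainConfig(), rate = 0,
                       verbose = FALSE) {
  stopifnot(inherits(model, "cpsModel"), is(cohort, "PatientCohort"))
  if (!length(cohortSplits(cohort)))
    stop("cohort has no split tags; run splitCohort() first")
  trIdx <- which(cohortSplits(cohort) == "train")
  vaIdx <- which(cohortSplits(cohort) == "val")
  if (!length(trIdx) || !length(vaIdx))
    stop("train and validation splits must be non-empty")
  y <- cohortLabels(cohort)
  if (length(unique(y[trIdx])) < 2L)
    stop("degenerate data: training split contains a single class")
  mode <- resolveMode(model$cfg, rate)
  inputs <- prepareInput(model, cohort)
  state <- adamInit(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  history <- data.frame(epoch = integer(), trainLoss = numeric(),
                        valLoss = numeric())
  withSeed(deriveSeed(tcfg$seed, "train"), {
    bad <- 0L
    for (epoch in seq_len(tcfg$maxEpochs)) {
      perm <- trIdx[sample.int(length(trIdx))]
      batches <- split(perm, ceiling(seq_along(perm) / tcfg$batchSize))
      eLoss <- 0
      for (bi in batches) {
        fw <- batchFwd(model, inputs, bi, train = TRUE, mode = mode)
        yb <- y[bi]
        dz <- (fw$probs - yb) / length(bi)
        grads <- batchBwd(model, inputs, fw, dz)
        upd <- adamStep(model$params, grads, state, lr = tcfg$lr)
        model$params <- upd$params
        state <- upd$state
        eLoss <- eLoss + bceLoss(fw$probs, yb) * length(bi)
      }
      eLoss <- eLoss / length(trIdx)
      vfw <- batchFwd(model, inputs, vaIdx, train = FALSE, mode = mode)
      vLoss <- bceLoss(vfw$probs, y[vaIdx])
      history[nrow(history) + 1L, ] <- list(epoch, eLoss, vLoss)
      if (verbose)
        message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, eLoss, vLoss))
      if (vLoss < best$loss - 1e-9) {
        best <- list(loss = vLoss, params = model$params, epoch = epoch)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (bad >= tcfg$patience) break
      }
    }
  })
  model$params <- best$params
  model$trained <- TRUE
  model$history <- history
  model$bestEpoch <- best$epoch
  model$rate <- rate
  model
}

#' Predicted positive-class probabilities
#'
#' @param model a trained `cpsModel`.
#' @param cohort a [PatientCohort].
#' @param split optional split tag to restrict to.
#' @param mcDropout keep dropout active (stochastic forward pass).
#' @param rate missingness rate (resolves the `auto` resampling mode).
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predictProb <- function(model, cohort, split = NULL, mcDropout = FALSE,
                        rate = NULL) {
  if (!is.null(split)) cohort <- subsetSplit(cohort, split)
  if (is.null(rate)) rate <- if (is.null(model$rate)) 0 else model$rate
  inputs <- prepareInput(model, cohort)
  idx <- seq_len(nPatients(cohort))
  out <- numeric(length(idx))
  mode <- resolveMode(model$cfg, rate)
  ## evaluate in blocks to bound cache memory
  for (blk in split(idx, ceiling(seq_along(idx) / 256L))) {
    fw <- batchFwd(model, inputs, blk, train = mcDropout, mode = mode)
    out[blk] <- fw$probs
  }
  out
}

## ---- metrics ---------------------------------------------------------------

#' Area under the ROC curve (rank statistic)
#'
#' Computed as the normalised Mann-Whitney rank statistic; ties contribute
#' 1/2 (so a constant score yields 0.5).
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels 0/1 labels.
#' @export
computeAUROC <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stop("AUROC undefined: a single class is present")
  r <- rank(scores)
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision; tied scores are processed as one block using
#' the block-end precision.
#'
#' @inheritParams computeAUROC
#' @export
computeAUPRC <- function(scores, labels) {
  labels <- as.integer(labels)
  nPos <- sum(labels == 1L)
  if (nPos == 0L || nPos == length(labels))
    stop("AUPRC undefined: a single class is present")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; l <- labels[o]
  ap <- 0; tp <- 0; seen <- 0
  i <- 1L
  n <- length(s)
  while (i <= n) {
    j <- i
    while (j < n && s[j + 1L] == s[i]) j <- j + 1L
    tpBlock <- sum(l[i:j])
    tp <- tp + tpBlock
    seen <- j
    if (tpBlock > 0) ap <- ap + (tp / seen) * (tpBlock / nPos)
    i <- j + 1L
  }
  ap
}

#' Evaluate a trained model on one split
#'
#' @param model a trained `cpsModel`.
#' @param cohort a tagged [PatientCohort].
#' @param split split tag (default `"test"`).
#' @return A list with `auroc`, `auprc`, `accuracy` (threshold 0.5), `n` and
#'   `prevalence`.
#' @export
evaluateModel <- function(model, cohort, split = "test") {
  sub <- subsetSplit(cohort, split)
  y <- cohortLabels(sub)
  if (length(unique(y)) < 2L)
    stop("metric undefined: split '", split, "' contains a single class")
  p <- predictProb(model, sub)
  list(auroc = computeAUROC(p, y), auprc = computeAUPRC(p, y),
       accuracy = mean((p >= 0.5) == (y == 1L)),
       n = length(y), prevalence = mean(y))
}

#' Irregularity experiment grid
#'
#' For every (model kind, missingness rate, seed): induce missingness on the
#' whole cohort (train/val/test consistently; the same thinned series are
#' shared across kinds so comparisons are paired), train with the kind's
#' imputation path (carry-forward or continuous resampling), and evaluate on
#' the test split.
#'
#' @param cohort a fully observed, split-tagged [PatientCohort].
#' @param kinds character vector of model kinds.
#' @param rates missingness rates, subset of `{0, 0.25, 0.5, 0.75}` by
#'   default.
#' @param seeds integer vector of run seeds (default `1:5`); each seed
#'   reseeds model initialisation, training and the missingness draw.
#' @param tcfg a [trainConfig()] (its seed is overridden per run).
#' @param cfgFor optional function `(kind, seed) -> modelConfig` to customise
#'   per-kind settings.
#' @param verbose print progress lines.
#' @return A tidy data.frame with columns kind, rate, seed, auroc, auprc,
#'   accuracy.
#' @export
irregularityExperiment <- function(cohort, kinds = c("coper", "ctransformer",
                                                     "perceiver", "lstm_cf"),
                                   rates = c(0, 0.25, 0.5, 0.75),
                                   seeds = 1:5, tcfg = trainConfig(),
                                   cfgFor = NULL, verbose = FALSE) {
  stopifnot(all(rates >= 0 & rates < 1))
  if (is.null(cfgFor))
    cfgFor <- function(kind, seed) modelConfig(kind = kind, seed = seed)
  T <- length(seriesTimes(cohortSeries(cohort)[[1L]]))
  D <- nFeatures(cohort)
  out <- list()
  for (seed in seeds) {
    for (rate in rates) {
      thinned <- if (rate > 0) {
        sers <- lapply(cohortSeries(cohort), dropTimeSteps, rate = rate,
                       seed = deriveSeed(seed, sprintf("miss%.2f", rate)))
        patientCohort(sers, cohortLabels(cohort), cohortSplits(cohort),
                      cohortMetadata(cohort))
      } else cohort
      for (kind in kinds) {
        cfg <- cfgFor(kind, seed)
        model <- buildModel(cfg, T, D)
        tc <- tcfg; tc$seed <- seed
        model <- trainModel(model, thinned, tc, rate = rate)
        ev <- evaluateModel(model, thinned, "test")
        out[[length(out) + 1L]] <-
          data.frame(kind = kind, rate = rate, seed = seed,
                     auroc = ev$auroc, auprc = ev$auprc,
                     accuracy = ev$accuracy)
        if (verbose)
          message(sprintf("kind=%s rate=%.2f seed=%d auroc=%.3f (epoch %d)",
                          kind, rate, seed, ev$auroc, model$bestEpoch))
      }
    }
  }
  do.call(rbind, out)
}
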