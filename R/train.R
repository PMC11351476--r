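# Data splitting, model fitting with early stopping, random
# hyperparameter search, and the three subject-specific training
# paradigms (montage-specific, cross-montage, pre-train/fine-tune).

# ---- trainable-parameter bookkeeping --------------------------------------

flattenParams <- function(model) {
  out <- list()
  for (i in seq_along(model@params$branches)) {
    pb <- model@params$branches[[i]]
    p <- paste0("b", i, ".")
    out[[paste0(p, "Wt")]] <- pb$Wt
    out[[paste0(p, "Ws")]] <- pb$Ws
    out[[paste0(p, "Wd")]] <- pb$Wd
    out[[paste0(p, "Wp")]] <- pb$Wp
    out[[paste0(p, "g1")]] <- pb$bn1$gamma
    out[[paste0(p, "b1")]] <- pb$bn1$beta
    out[[paste0(p, "g2")]] <- pb$bn2$gamma
    out[[paste0(p, "b2")]] <- pb$bn2$beta
    out[[paste0(p, "g3")]] <- pb$bn3$gamma
    out[[paste0(p, "b3")]] <- pb$bn3$beta
  }
  out$Wfc <- model@params$Wfc
  out$bfc <- model@params$bfc
  out
}

unflattenParams <- function(model, flat) {
  for (i in seq_along(model@params$branches)) {
    p <- paste0("b", i, ".")
    model@params$branches[[i]]$Wt <- flat[[paste0(p, "Wt")]]
    model@params$branches[[i]]$Ws <- flat[[paste0(p, "Ws")]]
    model@params$branches[[i]]$Wd <- flat[[paste0(p, "Wd")]]
    model@params$branches[[i]]$Wp <- flat[[paste0(p, "Wp")]]
    model@params$branches[[i]]$bn1$gamma <- flat[[paste0(p, "g1")]]
    model@params$branches[[i]]$bn1$beta <- flat[[paste0(p, "b1")]]
    model@params$branches[[i]]$bn2$gamma <- flat[[paste0(p, "g2")]]
    model@params$branches[[i]]$bn2$beta <- flat[[paste0(p, "b2")]]
    model@params$branches[[i]]$bn3$gamma <- flat[[paste0(p, "g3")]]
    model@params$branches[[i]]$bn3$beta <- flat[[paste0(p, "b3")]]
  }
  model@params$Wfc <- flat$Wfc
  model@params$bfc <- flat$bfc
  model
}

flattenGrads <- function(branchGrads, dWfc, dbfc) {
  out <- list()
  for (i in seq_along(branchGrads)) {
    g <- branchGrads[[i]]
    p <- paste0("b", i, ".")
    out[[paste0(p, "Wt")]] <- g$Wt; out[[paste0(p, "Ws")]] <- g$Ws
    out[[paste0(p, "Wd")]] <- g$Wd; out[[paste0(p, "Wp")]] <- g$Wp
    out[[paste0(p, "g1")]] <- g$g1; out[[paste0(p, "b1")]] <- g$b1
    out[[paste0(p, "g2")]] <- g$g2; out[[paste0(p, "b2")]] <- g$b2
    out[[paste0(p, "g3")]] <- g$g3; out[[paste0(p, "b3")]] <- g$b3
  }
  out$Wfc <- dWfc
  out$bfc <- dbfc
  out
}

# L2 weight decay applies to convolution/dense weights, not to batch-norm
# scale/shift or the dense bias.
decayedNames <- function(flat)
  grep("(Wt|Ws|Wd|Wp|Wfc)$", names(flat), value = TRUE)

optimInit <- function(flat, optimizer) {
  zeros <- lapply(flat, function(p) p * 0)
  if (optimizer == "adam") list(m = zeros, v = zeros, t = 0L)
  else list(v = zeros)
}

optimStep <- function(flat, grads, state, tcfg) {
  lr <- tcfg@learningRate
  wd <- tcfg@weightDecay
  dec <- decayedNames(flat)
  for (nm in dec) grads[[nm]] <- grads[[nm]] + wd * flat[[nm]]
  if (tcfg@optimizer == "adam") {
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    state$t <- state$t + 1L
    corr1 <- 1 - b1 ^ state$t
    corr2 <- 1 - b2 ^ state$t
    for (nm in names(flat)) {
      state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * grads[[nm]]
      state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * grads[[nm]] ^ 2
      flat[[nm]] <- flat[[nm]] - lr * (state$m[[nm]] / corr1) /
        (sqrt(state$v[[nm]] / corr2) + eps)
    }
  } else {
    mom <- 0.9
    for (nm in names(flat)) {
      state$v[[nm]] <- mom * state$v[[nm]] - lr * grads[[nm]]
      flat[[nm]] <- flat[[nm]] + state$v[[nm]]
    }
  }
  list(flat = flat, state = state)
}

# ---- splits ----------------------------------------------------------------

#' Stratified train/validation/test splits
#'
#' Holds out \code{testFrac} of the trials, stratified by response label
#' (and additionally by montage when \code{montages} is given, enforcing
#' an equal distribution of each montage's trials across splits), then
#' partitions the remainder into \code{nFolds} cross-validation folds,
#' each serving as validation exactly once. Deterministic given
#' \code{seed}.
#'
#' @param labels per-trial labels (factor or character).
#' @param montages optional per-trial montage labels for joint
#'   stratification.
#' @param seed split seed.
#' @param testFrac held-out fraction.
#' @param nFolds number of cross-validation folds.
#' @return a \linkS4class{SplitSpec}.
#' @examples
#' sp <- makeSplits(rep(c("left", "right"), each = 120), seed = 1)
#' length(sp@testIdx)                # 48
#' @export
makeSplits <- function(labels, montages = NULL, seed = 1L, testFrac = 0.2,
                       nFolds = 5L) {
  labels <- factor(as.character(labels), levels = c("left", "right"))
  if (any(table(labels) == 0L)) stop("both response classes must be present")
  strata <- if (is.null(montages)) labels else
    interaction(labels, montages, drop = TRUE)
  testIdx <- integer()
  folds <- replicate(nFolds, list(train = integer(), val = integer()),
                     simplify = FALSE)
  foldsOf <- vector("list", nFolds)
  withSeed(deriveSeed(seed, "split"), {
    for (s in seq_along(levels(strata))) {
      idx <- which(strata == levels(strata)[s])
      idx <- idx[sample.int(length(idx))]
      nTest <- round(testFrac * length(idx))
      testIdx <- c(testIdx, idx[seq_len(nTest)])
      rest <- idx[setdiff(seq_along(idx), seq_len(nTest))]
      # round-robin with a stratum-dependent starting fold, so fold sizes
      # stay within one trial of each other overall
      assign <- ((seq_along(rest) - 1L + (s - 1L)) %% nFolds) + 1L
      for (k in seq_len(nFolds))
        foldsOf[[k]] <- c(foldsOf[[k]], rest[assign == k])
    }
  })
  for (k in seq_len(nFolds))
    folds[[k]] <- list(train = sort(unlist(foldsOf[-k])),
                       val = sort(foldsOf[[k]]))
  new("SplitSpec", testIdx = sort(as.integer(testIdx)), folds = folds,
      strata = strata)
}

# ---- fitting ---------------------------------------------------------------

bceLoss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

labelsTo01 <- function(labels) as.numeric(labels == "right")

subsetX <- function(Xs, idx) lapply(Xs, function(a)
  a[, , idx, drop = FALSE])

#' Evaluate a model on labelled trials
#'
#' @param model a \linkS4class{CnnModel}.
#' @param X input array or list of arrays (one per backbone).
#' @param labels per-trial labels.
#' @return list with \code{accuracy}, \code{auroc}, \code{loss},
#'   \code{n}, \code{nCorrect}, \code{scores}.
#' @export
evaluateModel <- function(model, X, labels) {
  labels <- factor(as.character(labels), levels = c("left", "right"))
  p <- predictProb(model, X)
  pred <- predictLabel(p, model@configs[[1L]]@threshold)
  nCorrect <- sum(pred == labels)
  list(accuracy = nCorrect / length(labels),
       auroc = if (length(unique(labels)) == 2L)
         aurocScore(p, labels) else NA_real_,
       loss = bceLoss(p, labelsTo01(labels)),
       n = length(labels), nCorrect = nCorrect, scores = p)
}

#' Fit the CNN with early stopping
#'
#' Minimizes binary cross-entropy by minibatch gradient descent (Adam or
#' SGD with momentum), projecting the weights onto their max-norm balls
#' after every optimizer step, monitoring the configured validation
#' metric each epoch, and restoring the weights of the best validation
#' epoch on return. A zero learning rate performs no state updates of any
#' kind (evaluation only). Fully deterministic given
#' \code{tcfg@@seed}.
#'
#' @param model a freshly built (or pre-trained) \linkS4class{CnnModel}.
#' @param X (C, T, n) array or list of arrays per backbone.
#' @param labels all per-trial labels.
#' @param trainIdx,valIdx disjoint trial indices.
#' @param tcfg a \linkS4class{TrainConfig}.
#' @param testIdx optional held-out indices; metrics of the restored
#'   model are recorded without ever influencing training.
#' @param fold fold index recorded in the result.
#' @return a \linkS4class{TrainRun}.
#' @export
fitNetwork <- function(model, X, labels, trainIdx, valIdx, tcfg,
                       testIdx = NULL, fold = 1L) {
  stopifnot(!length(intersect(trainIdx, valIdx)))
  labels <- factor(as.character(labels), levels = c("left", "right"))
  Xs <- lapply(asBranchList(model, X), as3d)
  yAll <- labelsTo01(labels)
  Xtr <- subsetX(Xs, trainIdx); ytr <- yAll[trainIdx]
  Xval <- subsetX(Xs, valIdx); lval <- labels[valIdx]
  maximize <- tcfg@earlyStopMetric != "loss"
  best <- list(metric = if (maximize) -Inf else Inf, params = model@params,
               epoch = 0L)
  hist <- vector("list", tcfg@maxEpochs)
  nTr <- length(trainIdx)

  withSeed(deriveSeed(tcfg@seed, "fit", fold), {
    state <- optimInit(flattenParams(model), tcfg@optimizer)
    wait <- 0L
    for (epoch in seq_len(tcfg@maxEpochs)) {
      trainLoss <- NA_real_
      if (tcfg@learningRate > 0) {
        ord <- sample.int(nTr)
        losses <- numeric()
        for (start in seq(1L, nTr, by = tcfg@batchSize)) {
          idx <- ord[start:min(start + tcfg@batchSize - 1L, nTr)]
          Xb <- subsetX(Xtr, idx)
          yb <- ytr[idx]
          fw <- cnnForward(model, if (length(Xb) == 1L) Xb[[1L]] else Xb,
                           training = TRUE, keepCache = TRUE)
          model <- fw$model                       # refreshed BN statistics
          if (any(!is.finite(fw$prob)))
            stop("non-finite loss during training; aborting run")
          losses <- c(losses, bceLoss(fw$prob, yb))
          dz <- (fw$prob - yb) / length(yb)
          dWfc <- matrix(dz, 1L) %*% t(fw$feat)
          dbfc <- sum(dz)
          dFeat <- crossprod(model@params$Wfc, matrix(dz, 1L))
          offsets <- cumsum(c(0L, vapply(model@configs, featureLength,
                                         integer(1))))
          bg <- vector("list", length(model@configs))
          for (i in seq_along(model@configs)) {
            rows <- (offsets[i] + 1L):offsets[i + 1L]
            bg[[i]] <- branchBackward(model@params$branches[[i]],
                                      model@configs[[i]], fw$caches[[i]],
                                      dFeat[rows, , drop = FALSE])$grads
          }
          flat <- flattenParams(model)
          stepped <- optimStep(flat, flattenGrads(bg, dWfc, dbfc), state,
                               tcfg)
          state <- stepped$state
          model <- constrainWeights(unflattenParams(model, stepped$flat))
        }
        trainLoss <- mean(losses)
      }
      vm <- evaluateModel(model, if (length(Xval) == 1L) Xval[[1L]] else
        Xval, lval)
      metric <- switch(tcfg@earlyStopMetric, accuracy = vm$accuracy,
                       auroc = vm$auroc, loss = vm$loss)
      hist[[epoch]] <- data.frame(epoch = epoch, trainLoss = trainLoss,
                                  valLoss = vm$loss,
                                  valAccuracy = vm$accuracy,
                                  valAuroc = vm$auroc)
      improved <- if (maximize) metric > best$metric else metric < best$metric
      if (improved) {
        best <- list(metric = metric, params = model@params, epoch = epoch)
        wait <- 0L
      } else wait <- wait + 1L
      if (wait >= tcfg@patience) break
    }
  })
  model@params <- best$params
  metrics <- list(valMetric = best$metric,
                  earlyStopMetric = tcfg@earlyStopMetric)
  val <- evaluateModel(model, if (length(Xval) == 1L) Xval[[1L]] else Xval,
                       lval)
  metrics$valAccuracy <- val$accuracy
  metrics$valAuroc <- val$auroc
  if (!is.null(testIdx) && length(testIdx)) {
    tm <- evaluateModel(model, {
      Xt <- subsetX(Xs, testIdx)
      if (length(Xt) == 1L) Xt[[1L]] else Xt
    }, labels[testIdx])
    metrics$testAccuracy <- tm$accuracy
    metrics$testAuroc <- tm$auroc
    metrics$nTest <- tm$n
    metrics$nCorrect <- tm$nCorrect
    metrics$testScores <- tm$scores
    metrics$testLabels <- as.character(labels[testIdx])
  } else {
    metrics$testAccuracy <- NA_real_
    metrics$testAuroc <- NA_real_
    metrics$nTest <- 0L
    metrics$nCorrect <- 0L
  }
  new("TrainRun", model = model, history = do.call(rbind, hist),
      bestEpoch = best$epoch, metrics = metrics, fold = as.integer(fold),
      seed = tcfg@seed)
}

# Fit one model per cross-validation fold, sharing a configuration.
fitFolds <- function(mcfg, X, labels, split, tcfg, buildSeed = 1L) {
  runs <- vector("list", length(split@folds))
  for (k in seq_along(split@folds)) {
    model <- buildNetwork(mcfg, seed = deriveSeed(buildSeed, "fold", k))
    tk <- tcfg
    tk@seed <- deriveSeed(tcfg@seed, "fold", k)
    runs[[k]] <- fitNetwork(model, X, labels, split@folds[[k]]$train,
                            split@folds[[k]]$val, tk,
                            testIdx = split@testIdx, fold = k)
  }
  runs
}

foldMetricsTable <- function(runs) {
  data.frame(
    fold = vapply(runs, function(r) r@fold, integer(1)),
    valAccuracy = vapply(runs, function(r) r@metrics$valAccuracy, numeric(1)),
    testAccuracy = vapply(runs, function(r) r@metrics$testAccuracy,
                          numeric(1)),
    testAuroc = vapply(runs, function(r) r@metrics$testAuroc, numeric(1)),
    nTest = vapply(runs, function(r) r@metrics$nTest, integer(1)),
    nCorrect = vapply(runs, function(r) r@metrics$nCorrect, integer(1)))
}

# ---- random hyperparameter search -----------------------------------------

#' Default hyperparameter search space
#'
#' Candidate sets and log-uniform ranges for the random search over
#' architecture (F1, D, F2), optimizer, learning rate, weight decay and
#' early-stopping metric.
#'
#' @return a list understood by \code{\link{randomSearch}}.
#' @export
defaultSearchSpace <- function() {
  list(F1 = c(4L, 8L, 16L), D = c(1L, 2L, 4L), F2 = c(8L, 16L, 32L),
       optimizer = c("adam", "sgd"), lrRange = c(1e-4, 1e-2),
       wdRange = c(1e-6, 1e-3),
       earlyStopMetric = c("accuracy", "auroc", "loss"))
}

sampleConfigs <- function(space, nConfigs, seed) {
  withSeed(deriveSeed(seed, "search"), {
    lapply(seq_len(nConfigs), function(i) list(
      F1 = sample(space$F1, 1L), D = sample(space$D, 1L),
      F2 = sample(space$F2, 1L),
      optimizer = sample(space$optimizer, 1L),
      learningRate = exp(stats::runif(1, log(space$lrRange[1]),
                                      log(space$lrRange[2]))),
      weightDecay = exp(stats::runif(1, log(space$wdRange[1]),
                                     log(space$wdRange[2]))),
      earlyStopMetric = sample(space$earlyStopMetric, 1L)))
  })
}

applyConfig <- function(mcfg, tcfg, hp) {
  mcfg@F1 <- hp$F1; mcfg@D <- hp$D; mcfg@F2 <- hp$F2
  tcfg@optimizer <- hp$optimizer
  tcfg@learningRate <- hp$learningRate
  tcfg@weightDecay <- hp$weightDecay
  tcfg@earlyStopMetric <- hp$earlyStopMetric
  list(mcfg = mcfg, tcfg = tcfg)
}

#' Random hyperparameter search
#'
#' Samples \code{nConfigs} hyperparameter configurations, trains each with
#' \code{nIterations} random initializations on the first
#' cross-validation fold, and selects the configuration with the highest
#' validation accuracy averaged over iterations (ties broken by lower
#' configuration index).
#'
#' @param space candidate sets, see \code{\link{defaultSearchSpace}}.
#' @param X input array or list of arrays.
#' @param labels per-trial labels.
#' @param split a \linkS4class{SplitSpec}.
#' @param mcfg,tcfg base configurations overridden by each candidate.
#' @param nConfigs,nIterations search size.
#' @param seed search seed.
#' @return list with \code{bestIndex}, \code{bestConfig} (the sampled
#'   hyperparameters), \code{mcfg}, \code{tcfg} (base configs with the
#'   winning values applied), and \code{runs} (audit table of every
#'   config x iteration validation accuracy).
#' @export
randomSearch <- function(space, X, labels, split, mcfg = modelConfig(),
                         tcfg = trainConfig(), nConfigs = 50L,
                         nIterations = 3L, seed = 1L) {
  if (!length(space)) stop("empty search space")
  configs <- sampleConfigs(space, nConfigs, seed)
  rows <- list()
  means <- numeric(nConfigs)
  for (ci in seq_len(nConfigs)) {
    ap <- applyConfig(mcfg, tcfg, configs[[ci]])
    accs <- numeric(nIterations)
    for (it in seq_len(nIterations)) {
      model <- buildNetwork(ap$mcfg, seed = deriveSeed(seed, "init", ci, it))
      tk <- ap$tcfg
      tk@seed <- deriveSeed(seed, "searchfit", ci, it)
      run <- fitNetwork(model, X, labels, split@folds[[1L]]$train,
                        split@folds[[1L]]$val, tk)
      accs[it] <- run@metrics$valAccuracy
      rows[[length(rows) + 1L]] <- data.frame(config = ci, iteration = it,
                                              valAccuracy = accs[it])
    }
    means[ci] <- mean(accs)
  }
  bestIndex <- which.max(means)      # first maximum = lowest config index
  ap <- applyConfig(mcfg, tcfg, configs[[bestIndex]])
  list(bestIndex = bestIndex, bestConfig = configs[[bestIndex]],
       mcfg = ap$mcfg, tcfg = ap$tcfg, meanValAccuracy = means,
       runs = do.call(rbind, rows))
}

# ---- paradigm helpers ------------------------------------------------------

# Accepts the output of generateSubjectDataset() or a plain named list of
# TrialSets and returns the named list of TrialSets for one modality.
modalitySets <- function(subjectData, modality) {
  out <- lapply(subjectData, function(el) {
    if (is(el, "TrialSet")) el
    else if (!is.null(el[[modality]])) el[[modality]]
    else stop("no ", modality, " TrialSet for a montage")
  })
  if (is.null(names(out)) || any(!nzchar(names(out))))
    names(out) <- LETTERS[seq_along(out)]
  out
}

bindTrials <- function(sets) {
  d <- dim(trialData(sets[[1L]]))
  X <- array(unlist(lapply(sets, trialData)),
             c(d[1L], d[2L], sum(vapply(sets, nTrials, integer(1)))))
  labels <- factor(unlist(lapply(sets, function(s)
    as.character(trialLabels(s)))), levels = c("left", "right"))
  montage <- unlist(mapply(function(s, nm) rep(nm, nTrials(s)),
                           sets, names(sets), SIMPLIFY = FALSE))
  list(X = X, labels = labels, montage = unname(montage))
}

# ---- training paradigms ----------------------------------------------------

#' Montage-specific training paradigm
#'
#' Trains a separate subject-specific model on each montage's trials
#' alone (label-stratified 20% test split, 5-fold cross-validation of the
#' remainder), then selects the "best montage" by mean validation
#' accuracy only — never by test performance — and reports that montage's
#' held-out fold-model test metrics.
#'
#' @param subjectData output of \code{\link{generateSubjectDataset}} or a
#'   named list of \linkS4class{TrialSet}s (one per montage).
#' @param modality which modality to use.
#' @param mcfg,tcfg model and training configuration.
#' @param seed seed controlling splits and initializations.
#' @param searchSpace optional \code{\link{randomSearch}} space; when
#'   given, a per-montage search precedes the fold fits.
#' @param nConfigs,nIterations search size when \code{searchSpace} given.
#' @param nFolds cross-validation folds.
#' @return list with \code{perMontage} (runs, fold metrics, mean
#'   validation/test metrics per montage), \code{bestMontage}, and
#'   \code{best} (the selected montage's fold metric table and summary).
#' @export
runMontageSpecific <- function(subjectData, modality = "phase",
                               mcfg = modelConfig(), tcfg = trainConfig(),
                               seed = 1L, searchSpace = NULL,
                               nConfigs = 10L, nIterations = 3L,
                               nFolds = 5L) {
  sets <- modalitySets(subjectData, modality)
  per <- list()
  for (m in names(sets)) {
    s <- sets[[m]]
    labels <- trialLabels(s)
    split <- makeSplits(labels, seed = deriveSeed(seed, "split", m),
                        nFolds = nFolds)
    mc <- mcfg; tc <- tcfg
    if (!is.null(searchSpace)) {
      sr <- randomSearch(searchSpace, trialData(s), labels, split, mcfg,
                         tcfg, nConfigs, nIterations,
                         seed = deriveSeed(seed, "search", m))
      mc <- sr$mcfg; tc <- sr$tcfg
    }
    tc@seed <- deriveSeed(seed, "train", m)
    runs <- fitFolds(mc, trialData(s), labels, split, tc,
                     buildSeed = deriveSeed(seed, "build", m))
    fm <- foldMetricsTable(runs)
    per[[m]] <- list(runs = runs, split = split, foldMetrics = fm,
                     valAccuracy = mean(fm$valAccuracy),
                     testAccuracy = mean(fm$testAccuracy),
                     testAuroc = mean(fm$testAuroc))
  }
  valAccs <- vapply(per, `[[`, numeric(1), "valAccuracy")
  best <- names(which.max(valAccs))
  list(perMontage = per, bestMontage = best, best = per[[best]])
}

#' Cross-montage training paradigm
#'
#' Pools the trials of every available montage into one training set with
#' splits stratified jointly by label and montage, so each montage is
#' equally represented in the training, validation and held-out test
#' sets, and fits a single model per fold.
#'
#' @inheritParams runMontageSpecific
#' @return list with \code{runs}, \code{split}, \code{foldMetrics} and
#'   mean validation/test metrics.
#' @export
runCrossMontage <- function(subjectData, modality = "phase",
                            mcfg = modelConfig(), tcfg = trainConfig(),
                            seed = 1L, nFolds = 5L) {
  sets <- modalitySets(subjectData, modality)
  if (length(sets) < 2L) stop("cross-montage training requires >= 2 montages")
  pooled <- bindTrials(sets)
  split <- makeSplits(pooled$labels, pooled$montage,
                      seed = deriveSeed(seed, "xsplit"), nFolds = nFolds)
  tc <- tcfg
  tc@seed <- deriveSeed(seed, "xtrain")
  runs <- fitFolds(mcfg, pooled$X, pooled$labels, split, tc,
                   buildSeed = deriveSeed(seed, "xbuild"))
  fm <- foldMetricsTable(runs)
  list(runs = runs, split = split, montage = pooled$montage,
       foldMetrics = fm, valAccuracy = mean(fm$valAccuracy),
       testAccuracy = mean(fm$testAccuracy), testAuroc = mean(fm$testAuroc))
}

#' Pre-train/fine-tune training paradigm
#'
#' Pre-trains a model on the pooled trials of every montage except the
#' target (montage-and-label stratified splits), then fine-tunes all
#' weights on the target montage's training split and evaluates on the
#' target montage's held-out test set. Fine-tuning with
#' \code{fineTuneEpochs = 0} evaluates the pre-trained model directly.
#'
#' @inheritParams runMontageSpecific
#' @param target the montage under evaluation.
#' @param fineTuneEpochs optional cap on fine-tuning epochs; NULL uses
#'   \code{tcfg@@maxEpochs}, 0 skips fine-tuning.
#' @return list with \code{pretrainRun}, \code{runs} (fine-tuned fold
#'   models), \code{foldMetrics} and mean test metrics.
#' @export
runPretrainFinetune <- function(subjectData, target, modality = "phase",
                                mcfg = modelConfig(), tcfg = trainConfig(),
                                seed = 1L, nFolds = 5L,
                                fineTuneEpochs = NULL) {
  sets <- modalitySets(subjectData, modality)
  if (!target %in% names(sets)) stop("target montage not in subject data")
  others <- sets[setdiff(names(sets), target)]
  if (!length(others)) stop("pre-training requires a non-target montage")
  pooled <- bindTrials(others)
  preSplit <- makeSplits(pooled$labels, pooled$montage,
                         seed = deriveSeed(seed, "presplit"),
                         nFolds = nFolds)
  tcPre <- tcfg
  tcPre@seed <- deriveSeed(seed, "pretrain")
  preModel <- buildNetwork(mcfg, seed = deriveSeed(seed, "prebuild"))
  preRun <- fitNetwork(preModel, pooled$X, pooled$labels,
                       preSplit@folds[[1L]]$train,
                       preSplit@folds[[1L]]$val, tcPre)

  s <- sets[[target]]
  labels <- trialLabels(s)
  split <- makeSplits(labels, seed = deriveSeed(seed, "ftsplit", target),
                      nFolds = nFolds)
  if (!is.null(fineTuneEpochs) && fineTuneEpochs == 0L) {
    tm <- evaluateModel(preRun@model,
                        trialData(s)[, , split@testIdx, drop = FALSE],
                        labels[split@testIdx])
    fm <- data.frame(fold = NA_integer_, valAccuracy = NA_real_,
                     testAccuracy = tm$accuracy, testAuroc = tm$auroc,
                     nTest = tm$n, nCorrect = tm$nCorrect)
    return(list(pretrainRun = preRun, preSplit = preSplit,
                pretrainSize = dim(pooled$X)[3L], runs = list(),
                split = split,
                foldMetrics = fm, testAccuracy = tm$accuracy,
                testAuroc = tm$auroc))
  }
  tcFt <- tcfg
  if (!is.null(fineTuneEpochs)) {
    tcFt@maxEpochs <- as.integer(fineTuneEpochs)
    tcFt@patience <- min(tcFt@patience, max(tcFt@maxEpochs - 1L, 1L))
  }
  runs <- vector("list", length(split@folds))
  for (k in seq_along(split@folds)) {
    model <- preRun@model                  # warm start, all weights free
    tk <- tcFt
    tk@seed <- deriveSeed(seed, "ft", target, k)
    runs[[k]] <- fitNetwork(model, trialData(s), labels,
                            split@folds[[k]]$train, split@folds[[k]]$val,
                            tk, testIdx = split@testIdx, fold = k)
  }
  fm <- foldMetricsTable(runs)
  list(pretrainRun = preRun, preSplit = preSplit,
       pretrainSize = dim(pooled$X)[3L], runs = runs, split = split,
       foldMetrics = fm,
       valAccuracy = mean(fm$valAccuracy),
       testAccuracy = mean(fm$testAccuracy), testAuroc = mean(fm$testAuroc))
}
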