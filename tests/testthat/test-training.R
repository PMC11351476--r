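# Splits, fitting with early stopping, random search, and the three
# subject-specific training paradigms.

test_that("splits follow the 20% / 5-fold arithmetic on 240 trials", {
  labels <- rep(c("left", "right"), each = 120)
  sp <- makeSplits(labels, seed = 1)
  expect_length(sp@testIdx, 48L)
  pool <- unlist(lapply(sp@folds, function(f) f$val))
  expect_length(pool, 192L)
  valSizes <- vapply(sp@folds, function(f) length(f$val), integer(1))
  expect_true(all(valSizes %in% 38:39))
  # stratification within one trial per stratum
  for (f in sp@folds) {
    tab <- table(labels[f$val])
    expect_lte(abs(tab[1] - tab[2]), 1L)
  }
  # test set exactly balanced
  expect_equal(as.vector(table(labels[sp@testIdx])), c(24L, 24L))
})

test_that("splits are deterministic and leak-free", {
  labels <- rep(c("left", "right"), 60)
  s1 <- makeSplits(labels, seed = 7)
  s2 <- makeSplits(labels, seed = 7)
  expect_identical(s1@testIdx, s2@testIdx)
  expect_identical(s1@folds, s2@folds)
  s3 <- makeSplits(labels, seed = 8)
  expect_false(identical(s1@testIdx, s3@testIdx))
  # test indices never appear in any fold
  all_fold <- unlist(lapply(s1@folds, unlist))
  expect_length(intersect(s1@testIdx, all_fold), 0L)
  # every pooled trial is validation exactly once
  vals <- unlist(lapply(s1@folds, function(f) f$val))
  expect_false(any(duplicated(vals)))
  expect_setequal(c(vals, s1@testIdx), seq_along(labels))
  expect_error(makeSplits(rep("left", 20)), "both response classes")
})

test_that("montage stratification balances montages across splits", {
  labels <- rep(c("left", "right"), 180)
  montage <- rep(c("A", "B", "C"), each = 120)
  sp <- makeSplits(labels, montage, seed = 2)
  expect_equal(as.vector(table(montage[sp@testIdx])), rep(24L, 3))
  for (f in sp@folds) {
    tab <- table(montage[f$val])
    expect_lte(diff(range(tab)), 2L)
  }
})

test_that("a separable planted effect is learned to training accuracy 1", {
  s <- toyTrialSet(48, amp = 2, noise = 0.05, seed = 1)
  X <- trialData(s); y <- trialLabels(s)
  tr <- 1:36; val <- 37:48
  m <- buildNetwork(tinyModelConfig(), seed = 1)
  run <- fitNetwork(m, X, y, tr, val, quickTrainConfig(maxEpochs = 30L,
                                                       patience = 29L,
                                                       seed = 3))
  trainAcc <- evaluateModel(run@model, X[, , tr], y[tr])$accuracy
  expect_equal(trainAcc, 1)
})

test_that("zero learning rate changes nothing and keeps metrics constant", {
  s <- toyTrialSet(24, seed = 2)
  X <- trialData(s); y <- trialLabels(s)
  m <- buildNetwork(tinyModelConfig(), seed = 4)
  before <- erosbci:::flattenParams(m)
  run <- fitNetwork(m, X, y, 1:16, 17:24,
                    quickTrainConfig(learningRate = 0, maxEpochs = 6L,
                                     patience = 3L, seed = 5))
  expect_identical(erosbci:::flattenParams(run@model), before)
  expect_true(all(run@history$valAccuracy == run@history$valAccuracy[1]))
  expect_true(all(run@history$valLoss == run@history$valLoss[1]))
})

test_that("fitting is deterministic given the seed", {
  s <- toyTrialSet(32, seed = 3)
  X <- trialData(s); y <- trialLabels(s)
  fitOnce <- function() {
    m <- buildNetwork(tinyModelConfig(dropout = 0.3), seed = 6)
    fitNetwork(m, X, y, 1:24, 25:32, quickTrainConfig(maxEpochs = 5L,
                                                      patience = 4L,
                                                      seed = 11))
  }
  r1 <- fitOnce(); r2 <- fitOnce()
  expect_identical(erosbci:::flattenParams(r1@model),
                   erosbci:::flattenParams(r2@model))
  expect_identical(r1@history, r2@history)
})

test_that("early stopping restores the best validation epoch", {
  s <- toyTrialSet(48, amp = 1, noise = 0.3, seed = 4)
  X <- trialData(s); y <- trialLabels(s)
  m <- buildNetwork(tinyModelConfig(), seed = 7)
  run <- fitNetwork(m, X, y, 1:36, 37:48,
                    quickTrainConfig(maxEpochs = 15L, patience = 14L,
                                     seed = 8))
  expect_equal(run@metrics$valAccuracy, max(run@history$valAccuracy))
  expect_equal(run@bestEpoch,
               which.max(run@history$valAccuracy))
})

test_that("label-shuffled training stays at chance on held-out trials", {
  set.seed(20)
  inside <- 0L
  nSeeds <- 6L
  for (sd in seq_len(nSeeds)) {
    s <- toyTrialSet(80, amp = 1.5, noise = 0.3, seed = 100 + sd)
    y <- trialLabels(s)[sample(80)]          # break the label-signal link
    sp <- makeSplits(y, seed = sd)
    m <- buildNetwork(tinyModelConfig(), seed = sd)
    run <- fitNetwork(m, trialData(s), y, sp@folds[[1]]$train,
                      sp@folds[[1]]$val, quickTrainConfig(seed = sd),
                      testIdx = sp@testIdx)
    n <- run@metrics$nTest
    band <- 1.96 * sqrt(0.25 / n)
    if (abs(run@metrics$testAccuracy - 0.5) <= band) inside <- inside + 1L
  }
  expect_gte(inside, nSeeds - 1L)
})

test_that("random search selects by mean validation accuracy with stable ties", {
  s <- toyTrialSet(48, amp = 2, noise = 0.1, seed = 5)
  X <- trialData(s); y <- trialLabels(s)
  sp <- makeSplits(y, seed = 3, nFolds = 2L)
  space <- list(F1 = 2L, D = 1L, F2 = 4L, optimizer = "adam",
                lrRange = c(1e-3, 1e-2), wdRange = c(1e-6, 1e-5),
                earlyStopMetric = "accuracy")
  base <- tinyModelConfig()
  tc <- quickTrainConfig(maxEpochs = 4L, patience = 3L)
  sr <- randomSearch(space, X, y, sp, base, tc, nConfigs = 3L,
                     nIterations = 2L, seed = 9)
  # selection equals brute-force argmax over the audit table
  means <- tapply(sr$runs$valAccuracy, sr$runs$config, mean)
  expect_equal(sr$bestIndex, unname(which.max(means)))
  expect_equal(unname(sr$meanValAccuracy), unname(as.numeric(means)))
  # a single-config space selects that config
  sr1 <- randomSearch(space, X, y, sp, base, tc, nConfigs = 1L,
                      nIterations = 1L, seed = 9)
  expect_equal(sr1$bestIndex, 1L)
  expect_error(randomSearch(list(), X, y, sp), "empty")
})

test_that("montage-specific paradigm picks the montage with best validation accuracy", {
  # montage B carries double the planted amplitude
  sA <- toyTrialSet(40, amp = 0.25, noise = 0.5, seed = 6)
  sB <- toyTrialSet(40, amp = 2.5, noise = 0.5, seed = 7)
  res <- runMontageSpecific(list(A = sA, B = sB), mcfg = tinyModelConfig(),
                            tcfg = quickTrainConfig(maxEpochs = 6L,
                                                    patience = 5L),
                            seed = 4, nFolds = 2L)
  # the selection rule itself: argmax of per-montage validation accuracy
  valAccs <- vapply(res$perMontage, `[[`, numeric(1), "valAccuracy")
  expect_identical(res$bestMontage, names(which.max(valAccs)))
  expect_identical(res$bestMontage, "B")
  # test metrics reported for the selected montage's fold models
  expect_equal(res$best$testAccuracy,
               mean(res$best$foldMetrics$testAccuracy))
})

test_that("cross-montage pooling stratifies montages and needs >= 2 montages", {
  sA <- toyTrialSet(40, seed = 8)
  sB <- toyTrialSet(40, seed = 9)
  sC <- toyTrialSet(40, seed = 10)
  res <- runCrossMontage(list(A = sA, B = sB, C = sC),
                         mcfg = tinyModelConfig(),
                         tcfg = quickTrainConfig(maxEpochs = 3L,
                                                 patience = 2L),
                         seed = 5, nFolds = 2L)
  # 120-trial pool, 8 test trials per montage (20%)
  expect_equal(sum(vapply(list(sA, sB, sC), nTrials, integer(1))), 120L)
  expect_equal(as.vector(table(res$montage[res$split@testIdx])), rep(8L, 3))
  for (f in res$split@folds)
    expect_lte(diff(range(table(res$montage[f$val]))), 2L)
  expect_error(runCrossMontage(list(A = sA)), ">= 2 montages")
})

test_that("pre-training excludes the target montage and 0-epoch fine-tuning is identity", {
  sA <- toyTrialSet(40, amp = 2, noise = 0.2, seed = 11)
  sB <- toyTrialSet(40, amp = 2, noise = 0.2, seed = 12)
  sC <- toyTrialSet(40, amp = 2, noise = 0.2, seed = 13)
  data <- list(A = sA, B = sB, C = sC)
  res0 <- runPretrainFinetune(data, target = "C",
                              mcfg = tinyModelConfig(),
                              tcfg = quickTrainConfig(maxEpochs = 5L,
                                                      patience = 4L),
                              seed = 6, nFolds = 2L, fineTuneEpochs = 0L)
  # index audit: the pre-training pool holds only montages A and B, and
  # every pre-training index stays inside that pool
  expect_equal(res0$pretrainSize, nTrials(sA) + nTrials(sB))
  preIdx <- c(res0$preSplit@testIdx, unlist(lapply(res0$preSplit@folds,
                                                   unlist)))
  expect_true(all(preIdx >= 1L & preIdx <= res0$pretrainSize))
  # 0-epoch fine-tuning equals evaluating the pre-trained model directly
  direct <- evaluateModel(res0$pretrainRun@model,
                          trialData(sC)[, , res0$split@testIdx],
                          trialLabels(sC)[res0$split@testIdx])
  expect_equal(res0$testAccuracy, direct$accuracy)
  expect_equal(res0$testAuroc, direct$auroc)
  expect_error(runPretrainFinetune(list(A = sA), target = "A"),
               "non-target")
  # warm-started fine-tuning transfers: the pre-trained model is already
  # above chance on the aligned target montage
  expect_gt(direct$auroc, 0.5)
})
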