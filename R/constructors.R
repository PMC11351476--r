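#' Create a simulation configuration
#'
#' Constructor for \linkS4class{SimConfig} with the study's default design:
#' 20 blocks of 24 trials per montage, half manual, sampled at 39.0625 Hz
#' over a 42-voxel two-hemisphere ROI, with the hand-lateralized effect
#' planted at 179 and 410 ms after the response in a right-hemisphere
#' "hand" voxel (and, weaker, its left-hemisphere mirror).
#'
#' @param nSubjects,nMontages,nBlocks,trialsPerBlock design counts.
#' @param manualFraction fraction of manual-response trials per block.
#' @param fs sampling rate (Hz).
#' @param nVoxels flattened ROI voxel count (even; half per hemisphere).
#' @param effectAmplitude planted effect amplitude (same units as noiseSd).
#' @param effectLatencies effect bump latencies (ms after response).
#' @param effectVoxel right-hemisphere voxel index carrying the effect.
#' @param effectSigmaMs Gaussian bump width (ms).
#' @param noiseSd single-channel white-noise SD.
#' @param pinkExponent,pinkScale 1/f noise slope and relative amplitude.
#' @param pulseFreq,pulseAmplitude pulse-artifact frequency (Hz)/amplitude.
#' @param voxelDropoutRange montage fraction of non-viable voxels, interval.
#' @param channelsPerVoxelRange channels per viable voxel, integer interval.
#' @param spatialOffsetMs per-montage latency jitter half-width (ms).
#' @param intensityEffectScale,intensityPinkScale intensity-modality
#'   effect attenuation and extra low-frequency noise.
#' @param seed base seed.
#' @return a validated \linkS4class{SimConfig}.
#' @examples
#' cfg <- simConfig(seed = 1)
#' cfg
#' @export
simConfig <- function(nSubjects = 1L, nMontages = 4L, nBlocks = 20L,
                      trialsPerBlock = 24L, manualFraction = 0.5,
                      fs = 39.0625, nVoxels = 42L, effectAmplitude = 1,
                      effectLatencies = c(179, 410), effectVoxel = 33L,
                      effectSigmaMs = 50, noiseSd = 1, pinkExponent = 1,
                      pinkScale = 1, pulseFreq = 1.2, pulseAmplitude = 0.5,
                      voxelDropoutRange = c(0.1, 0.3),
                      channelsPerVoxelRange = c(1L, 6L),
                      spatialOffsetMs = 0, intensityEffectScale = 0.5,
                      intensityPinkScale = 3, seed = 1L) {
  new("SimConfig", nSubjects = as.integer(nSubjects),
      nMontages = as.integer(nMontages), nBlocks = as.integer(nBlocks),
      trialsPerBlock = as.integer(trialsPerBlock),
      manualFraction = manualFraction, fs = fs,
      nVoxels = as.integer(nVoxels), effectAmplitude = effectAmplitude,
      effectLatencies = effectLatencies,
      effectVoxel = as.integer(effectVoxel), effectSigmaMs = effectSigmaMs,
      noiseSd = noiseSd, pinkExponent = pinkExponent, pinkScale = pinkScale,
      pulseFreq = pulseFreq, pulseAmplitude = pulseAmplitude,
      voxelDropoutRange = voxelDropoutRange,
      channelsPerVoxelRange = as.integer(channelsPerVoxelRange),
      spatialOffsetMs = spatialOffsetMs,
      intensityEffectScale = intensityEffectScale,
      intensityPinkScale = intensityPinkScale, seed = as.integer(seed))
}

#' Create a pre-processing configuration
#'
#' Defaults follow the fast-optical-signal chain: 0.1-12 Hz zero-phase
#' band-pass, 998 ms pre-response baseline, 716 ms crop half-window, and
#' channel inclusion iff source-detector distance lies in [2, 7] cm, phase
#' SD < 200 and mean raw AC > 100 mV.
#'
#' @param fs sampling rate (Hz).
#' @param band band-pass edges (Hz).
#' @param baselineMs baseline window duration (ms).
#' @param cropMs crop half-window (ms).
#' @param qcDistanceCm inclusive distance interval (cm).
#' @param qcPhaseSdMax phase-SD exclusion threshold (strict).
#' @param qcAcMinMv mean-AC inclusion threshold in mV (strict).
#' @param wrapPeriod phase units per modulation cycle.
#' @return a validated \linkS4class{PreprocessConfig}.
#' @export
preprocessConfig <- function(fs = 39.0625, band = c(0.1, 12),
                             baselineMs = 998, cropMs = 716,
                             qcDistanceCm = c(2, 7), qcPhaseSdMax = 200,
                             qcAcMinMv = 100, wrapPeriod = 360) {
  new("PreprocessConfig", fs = fs, band = band, baselineMs = baselineMs,
      cropMs = cropMs, qcDistanceCm = qcDistanceCm,
      qcPhaseSdMax = qcPhaseSdMax, qcAcMinMv = qcAcMinMv,
      wrapPeriod = wrapPeriod)
}

#' Create a network architecture configuration
#'
#' Defaults give the search-space centre (F1, D, F2) = (8, 2, 16) on a
#' 42 x 56 input, with (1, 20) temporal kernels, (1, 8) average pooling,
#' dropout 0.5, max-norm 1 on the spatial filters and 0.25 on the dense
#' weights, and a fixed decision threshold of 0.5.
#'
#' @param C,T input voxels and time samples.
#' @param F1,D,F2 temporal, spatial-per-temporal, and pointwise filters.
#' @param temporalKernel,separableKernel temporal kernel lengths (samples).
#' @param pool average-pooling width.
#' @param dropout dropout probability.
#' @param depthwiseMaxNorm,denseMaxNorm L2 max-norm bounds.
#' @param threshold decision threshold; outputs above it are "right".
#' @param activation "elu" or "linear" (diagnostic).
#' @return a validated \linkS4class{ModelConfig}.
#' @examples
#' countParameters(modelConfig())
#' @export
modelConfig <- function(C = 42L, T = 56L, F1 = 8L, D = 2L, F2 = 16L,
                        temporalKernel = 20L, separableKernel = 20L,
                        pool = 8L, dropout = 0.5, depthwiseMaxNorm = 1,
                        denseMaxNorm = 0.25, threshold = 0.5,
                        activation = "elu") {
  # assign slots directly: a named argument `C` to new() would partially
  # match its `Class` parameter
  obj <- new("ModelConfig")
  obj@C <- as.integer(C); obj@T <- as.integer(T)
  obj@F1 <- as.integer(F1); obj@D <- as.integer(D); obj@F2 <- as.integer(F2)
  obj@temporalKernel <- as.integer(temporalKernel)
  obj@separableKernel <- as.integer(separableKernel)
  obj@pool <- as.integer(pool); obj@dropout <- dropout
  obj@depthwiseMaxNorm <- depthwiseMaxNorm; obj@denseMaxNorm <- denseMaxNorm
  obj@threshold <- threshold; obj@activation <- activation
  validObject(obj)
  obj
}

#' Create a training configuration
#'
#' Defaults: up to 300 epochs of Adam on binary cross-entropy, batch size
#' 32, early stopping on validation accuracy with patience 50 and
#' best-epoch weight restoration.
#'
#' @param maxEpochs maximum passes over the training data.
#' @param optimizer "adam" or "sgd".
#' @param learningRate step size.
#' @param weightDecay L2 penalty.
#' @param earlyStopMetric "accuracy", "auroc" or "loss".
#' @param patience epochs without validation improvement before stopping.
#' @param batchSize minibatch size.
#' @param seed seed for initialization, shuffling and dropout.
#' @return a validated \linkS4class{TrainConfig}.
#' @export
trainConfig <- function(maxEpochs = 300L, optimizer = "adam",
                        learningRate = 1e-3, weightDecay = 1e-4,
                        earlyStopMetric = "accuracy", patience = 50L,
                        batchSize = 32L, seed = 1L) {
  new("TrainConfig", maxEpochs = as.integer(maxEpochs), optimizer = optimizer,
      learningRate = learningRate, weightDecay = weightDecay,
      earlyStopMetric = earlyStopMetric, patience = as.integer(patience),
      batchSize = as.integer(batchSize), seed = as.integer(seed))
}

#' Construct a TrialSet
#'
#' @param data numeric (C, T, n) array.
#' @param labels "left"/"right" per trial (character or factor).
#' @param blocks integer block index per trial (defaults to 1).
#' @param modality "phase" or "intensity".
#' @param subjectId,montageId metadata labels.
#' @param fs sampling rate (Hz).
#' @return a validated \linkS4class{TrialSet}.
#' @export
trialSet <- function(data, labels, blocks = NULL, modality = "phase",
                     subjectId = "S1", montageId = "A", fs = 39.0625) {
  n <- dim(data)[3L]
  if (is.null(blocks)) blocks <- rep(1L, n)
  new("TrialSet", data = data,
      labels = factor(as.character(labels), levels = c("left", "right")),
      blocks = as.integer(blocks), modality = modality,
      subjectId = subjectId, montageId = montageId, fs = fs)
}

# ---- accessors -------------------------------------------------------------

#' @describeIn trialSet the (C, T, n) data array.
#' @param x a TrialSet.
#' @export
trialData <- function(x) x@data

#' @describeIn trialSet the per-trial response labels.
#' @export
trialLabels <- function(x) x@labels

#' @describeIn trialSet the per-trial block indices.
#' @export
trialBlocks <- function(x) x@blocks

#' @describeIn trialSet number of trials.
#' @export
nTrials <- function(x) dim(x@data)[3L]

#' Viable-voxel mask of a montage
#' @param x a \linkS4class{MontageSpec}.
#' @export
viableVoxels <- function(x) x@viableVoxelMask

#' Channels mapping to each voxel of a montage
#' @param x a \linkS4class{MontageSpec}.
#' @export
channelsPerVoxel <- function(x) x@channelsPerVoxel

#' Relevance matrix of an attribution map
#' @param x an \linkS4class{AttributionMap}.
#' @export
relevance <- function(x) x@relevance

# ---- show methods ----------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nSubjects, "subject(s) x", object@nMontages,
      "montage(s);", object@nBlocks, "blocks x", object@trialsPerBlock,
      "trials (manual fraction", object@manualFraction, ")\n")
  cat("  grid:", object@nVoxels, "voxels; fs:", object@fs, "Hz; effect: A =",
      object@effectAmplitude, "at", paste(object@effectLatencies, collapse = "/"),
      "ms, voxel", object@effectVoxel, "\n")
  cat("  noise: white SD", object@noiseSd, ", pink x", object@pinkScale,
      "(1/f^", object@pinkExponent, "), pulse", object@pulseFreq, "Hz x",
      object@pulseAmplitude, "; seed", object@seed, "\n")
})

setMethod("show", "MontageSpec", function(object) {
  cat("MontageSpec", object@montageId, ":",
      sum(object@viableVoxelMask), "/", length(object@viableVoxelMask),
      "viable voxels; mean channels/viable voxel",
      round(mean(object@channelsPerVoxel[object@viableVoxelMask]), 2), "\n")
})

setMethod("show", "TrialSet", function(object) {
  d <- dim(object@data)
  cat("TrialSet:", d[3L], "trials of", d[1L], "voxels x", d[2L],
      "samples (", object@modality, ") subject", object@subjectId,
      "montage", object@montageId, "\n")
  cat("  labels:", sum(object@labels == "left"), "left /",
      sum(object@labels == "right"), "right; fs", object@fs, "Hz\n")
})

setMethod("show", "ModelConfig", function(object) {
  cat("ModelConfig: input (", object@C, "x", object@T, "), F1 =", object@F1,
      ", D =", object@D, ", F2 =", object@F2, "\n")
  cat("  kernels (1,", object@temporalKernel, ")/(1,",
      object@separableKernel, "), pool (1,", object@pool, "), dropout",
      object@dropout, ", threshold", object@threshold, "\n")
})

setMethod("show", "CnnModel", function(object) {
  cat("CnnModel with", length(object@configs), "backbone(s),",
      nTrainable(object), "trainable parameters\n")
  print(networkSpec(object@configs[[1L]]))
})

setMethod("show", "TrainRun", function(object) {
  cat("TrainRun (fold", object@fold, ", seed", object@seed, "): best epoch",
      object@bestEpoch, "\n  test accuracy",
      round(object@metrics$testAccuracy, 3), ", test AUROC",
      round(object@metrics$testAuroc, 3), "(n =", object@metrics$nTest, ")\n")
})

setMethod("show", "AttributionMap", function(object) {
  cat("AttributionMap", if (length(object@group)) paste0("[", object@group, "]"),
      ":", nrow(object@relevance), "x", ncol(object@relevance),
      "; sum =", signif(sum(object@relevance), 4),
      "; delta =", signif(object@delta, 4), "\n")
})
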