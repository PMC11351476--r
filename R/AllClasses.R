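#' @import methods
NULL

#' Simulation configuration for synthetic EROS datasets
#'
#' Holds every knob of the synthetic frequency-domain optical data
#' generator: the experimental design (blocks, trials per block, fraction of
#' manual-response trials), the sampling rate, the planted hand-lateralized
#' motor effect (amplitude, latencies, effect voxel), and the noise model
#' (white + 1/f pink noise, sinusoidal pulse artifact, montage quality
#' ranges).
#'
#' The default design mirrors a two-choice reaction-time session: 20 blocks
#' of 24 trials, half of them manual, giving 240 labelled trials per
#' montage at 39.0625 Hz.
#'
#' @slot nSubjects number of subjects to simulate.
#' @slot nMontages montages per subject (at most 4, labelled A-D).
#' @slot nBlocks recording blocks per montage.
#' @slot trialsPerBlock trials in each block (manual + vocal).
#' @slot manualFraction fraction of trials with a manual response; only
#'   manual trials yield labelled epochs.
#' @slot fs sampling rate in Hz.
#' @slot nVoxels flattened voxel count of the two-hemisphere ROI grid
#'   (split half/half between left and right hemisphere).
#' @slot effectAmplitude peak amplitude of the planted event-related
#'   deflection, in signal units (same units as \code{noiseSd}).
#' @slot effectLatencies latencies of the planted deflections in ms after
#'   the response.
#' @slot effectVoxel flattened index of the right-hemisphere "hand" voxel
#'   carrying the planted effect; its left-hemisphere mirror carries a
#'   weaker copy.
#' @slot effectSigmaMs temporal width (Gaussian sigma, ms) of each bump.
#' @slot noiseSd white-noise standard deviation per voxel (single-channel).
#' @slot pinkExponent spectral slope of the 1/f noise component.
#' @slot pinkScale amplitude of the pink-noise component relative to
#'   \code{noiseSd}.
#' @slot pulseFreq pulse-artifact frequency (Hz).
#' @slot pulseAmplitude pulse-artifact amplitude in signal units.
#' @slot voxelDropoutRange interval of the fraction of ROI voxels without
#'   viable channels for a montage.
#' @slot channelsPerVoxelRange integer interval of channels mapping to each
#'   viable voxel; per-voxel noise SD scales as 1/sqrt(channels).
#' @slot spatialOffsetMs per-montage jitter (uniform half-width, ms) of the
#'   planted latencies, emulating inter-montage misalignment.
#' @slot intensityEffectScale multiplier on the planted effect for the
#'   intensity modality (intensity is less discriminative than phase).
#' @slot intensityPinkScale multiplier on pink noise for intensity (its
#'   low-frequency contamination).
#' @slot seed base integer seed; all generated objects are deterministic
#'   functions of (seed, subject, montage).
#' @export
setClass("SimConfig", representation(
  nSubjects = "integer", nMontages = "integer", nBlocks = "integer",
  trialsPerBlock = "integer", manualFraction = "numeric", fs = "numeric",
  nVoxels = "integer", effectAmplitude = "numeric",
  effectLatencies = "numeric", effectVoxel = "integer",
  effectSigmaMs = "numeric", noiseSd = "numeric", pinkExponent = "numeric",
  pinkScale = "numeric", pulseFreq = "numeric", pulseAmplitude = "numeric",
  voxelDropoutRange = "numeric", channelsPerVoxelRange = "integer",
  spatialOffsetMs = "numeric", intensityEffectScale = "numeric",
  intensityPinkScale = "numeric", seed = "integer"
))

setValidity("SimConfig", function(object) {
  msg <- character()
  cnt <- c(nSubjects = object@nSubjects, nMontages = object@nMontages,
           nBlocks = object@nBlocks, trialsPerBlock = object@trialsPerBlock,
           nVoxels = object@nVoxels)
  if (any(cnt < 1L)) msg <- c(msg, "all counts must be positive")
  if (object@nMontages > 4L) msg <- c(msg, "at most 4 montages (A-D)")
  if (object@manualFraction <= 0 || object@manualFraction > 1)
    msg <- c(msg, "manualFraction must lie in (0, 1]")
  if (object@fs <= 0) msg <- c(msg, "fs must be positive")
  if (object@nVoxels %% 2L != 0L)
    msg <- c(msg, "nVoxels must be even (two hemispheres)")
  if (object@effectVoxel < 1L || object@effectVoxel > object@nVoxels)
    msg <- c(msg, "effectVoxel outside the voxel grid")
  if (object@effectVoxel <= object@nVoxels / 2L)
    msg <- c(msg, "effectVoxel must lie in the right hemisphere (upper half)")
  Tlen <- epochLength(object@fs)
  tms <- epochTimesMs(object@fs)
  if (any(object@effectLatencies < min(tms) | object@effectLatencies > max(tms)))
    msg <- c(msg, "effect latencies fall outside the epoch window")
  if (length(object@voxelDropoutRange) != 2L ||
      any(object@voxelDropoutRange < 0) || any(object@voxelDropoutRange >= 1) ||
      diff(object@voxelDropoutRange) < 0)
    msg <- c(msg, "voxelDropoutRange must be an interval within [0, 1)")
  if (length(object@channelsPerVoxelRange) != 2L ||
      any(object@channelsPerVoxelRange < 1L) ||
      diff(object@channelsPerVoxelRange) < 0L)
    msg <- c(msg, "channelsPerVoxelRange must be a positive integer interval")
  if (length(msg)) msg else TRUE
})

#' Montage quality specification
#'
#' Describes one optode placement (montage): which ROI voxels receive at
#' least one quality-passing channel, how many channels map to each viable
#' voxel, and the montage-specific latency jitter of the planted effect.
#'
#' @slot montageId montage label, "A".."D".
#' @slot viableVoxelMask logical vector over the flattened ROI grid.
#' @slot channelsPerVoxel integer vector; 0 exactly where the mask is FALSE.
#' @slot latencyOffsetMs latency jitter (ms) applied to the planted effect
#'   for this montage.
#' @export
setClass("MontageSpec", representation(
  montageId = "character", viableVoxelMask = "logical",
  channelsPerVoxel = "integer", latencyOffsetMs = "numeric"
))

setValidity("MontageSpec", function(object) {
  msg <- character()
  if (length(object@viableVoxelMask) != length(object@channelsPerVoxel))
    msg <- c(msg, "mask and channel counts must have equal length")
  if (any(object@channelsPerVoxel < 0L))
    msg <- c(msg, "channel counts must be non-negative")
  if (any(object@channelsPerVoxel[!object@viableVoxelMask] != 0L))
    msg <- c(msg, "non-viable voxels must have 0 channels")
  if (any(object@viableVoxelMask & object@channelsPerVoxel == 0L))
    msg <- c(msg, "viable voxels must have at least 1 channel")
  if (!object@montageId %in% LETTERS[1:4])
    msg <- c(msg, "montageId must be one of A-D")
  if (length(msg)) msg else TRUE
})

#' Labelled single-trial tensor set
#'
#' The pipeline's central currency: a voxel-by-time-by-trial array of
#' model-ready single trials, with per-trial response labels and block
#' indices, plus subject/montage/modality metadata.
#'
#' @slot data numeric array of dim (C voxels, T samples, n trials).
#' @slot labels factor with levels \code{c("left", "right")}, one per trial.
#' @slot blocks integer block index per trial.
#' @slot modality "phase" or "intensity".
#' @slot subjectId subject identifier.
#' @slot montageId montage label.
#' @slot fs sampling rate in Hz.
#' @export
setClass("TrialSet", representation(
  data = "array", labels = "factor", blocks = "integer",
  modality = "character", subjectId = "character", montageId = "character",
  fs = "numeric"
))

setValidity("TrialSet", function(object) {
  msg <- character()
  d <- dim(object@data)
  if (length(d) != 3L) msg <- c(msg, "data must be a 3-D (C, T, n) array")
  else {
    if (length(object@labels) != d[3L])
      msg <- c(msg, "labels length must equal trial count")
    if (length(object@blocks) != d[3L])
      msg <- c(msg, "blocks length must equal trial count")
  }
  if (!identical(levels(object@labels), c("left", "right")))
    msg <- c(msg, "labels must be a factor with levels left, right")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "trial data must be finite")
  if (!object@modality %in% c("phase", "intensity"))
    msg <- c(msg, "modality must be phase or intensity")
  if (length(msg)) msg else TRUE
})

#' Pre-processing configuration
#'
#' Parameters of the fast-optical-signal pre-processing chain: band edges,
#' baseline and crop windows, and channel quality-control thresholds.
#'
#' @slot fs sampling rate (Hz).
#' @slot band band-pass edges (Hz); canonical choices are (0.1, 12),
#'   (4, 7), (8, 13) and (13, 20).
#' @slot baselineMs duration of the pre-response baseline window (ms).
#' @slot cropMs half-window retained around the response (ms).
#' @slot qcDistanceCm inclusive source-detector distance interval (cm).
#' @slot qcPhaseSdMax channels must have phase SD strictly below this.
#' @slot qcAcMinMv channels must have mean raw AC strictly above this (mV).
#' @slot wrapPeriod phase units per modulation cycle, for unwrapping.
#' @export
setClass("PreprocessConfig", representation(
  fs = "numeric", band = "numeric", baselineMs = "numeric",
  cropMs = "numeric", qcDistanceCm = "numeric", qcPhaseSdMax = "numeric",
  qcAcMinMv = "numeric", wrapPeriod = "numeric"
))

setValidity("PreprocessConfig", function(object) {
  msg <- character()
  if (length(object@band) != 2L || object@band[1L] <= 0 ||
      object@band[2L] <= object@band[1L] || object@band[2L] >= object@fs / 2)
    msg <- c(msg, "band must satisfy 0 < low < high < fs/2")
  if (object@baselineMs <= 0 || object@cropMs <= 0)
    msg <- c(msg, "baselineMs and cropMs must be positive")
  if (length(object@qcDistanceCm) != 2L || diff(object@qcDistanceCm) < 0)
    msg <- c(msg, "qcDistanceCm must be an ordered interval")
  if (object@wrapPeriod <= 0) msg <- c(msg, "wrapPeriod must be positive")
  if (length(msg)) msg else TRUE
})

#' Network architecture configuration
#'
#' All architecture symbols of the compact depthwise-separable CNN: input
#' geometry (C voxels, T samples), filter counts (F1 temporal, D spatial
#' per temporal, F2 pointwise), kernel and pooling sizes, dropout, the
#' max-norm constraints, and the decision threshold.
#'
#' @slot C flattened voxel count of the input.
#' @slot T time samples of the input.
#' @slot F1 number of temporal convolution filters.
#' @slot D spatial (depthwise) filters per temporal filter.
#' @slot F2 pointwise filters of the separable convolution.
#' @slot temporalKernel temporal kernel length (samples).
#' @slot separableKernel depthwise temporal kernel of the separable stage.
#' @slot pool average-pooling width (samples).
#' @slot dropout dropout probability.
#' @slot depthwiseMaxNorm L2 max-norm bound on each spatial filter.
#' @slot denseMaxNorm L2 max-norm bound on the dense weight vector.
#' @slot threshold decision threshold on the sigmoid output; outputs
#'   strictly above it are classified "right".
#' @slot activation "elu" (default) or "linear" (diagnostic, used to
#'   verify attribution against closed-form linear contributions).
#' @export
setClass("ModelConfig", representation(
  C = "integer", T = "integer", F1 = "integer", D = "integer",
  F2 = "integer", temporalKernel = "integer", separableKernel = "integer",
  pool = "integer", dropout = "numeric", depthwiseMaxNorm = "numeric",
  denseMaxNorm = "numeric", threshold = "numeric", activation = "character"
), prototype = prototype(
  C = 42L, T = 56L, F1 = 8L, D = 2L, F2 = 16L, temporalKernel = 20L,
  separableKernel = 20L, pool = 8L, dropout = 0.5, depthwiseMaxNorm = 1,
  denseMaxNorm = 0.25, threshold = 0.5, activation = "elu"
))

setValidity("ModelConfig", function(object) {
  msg <- character()
  if (any(c(object@C, object@T, object@F1, object@D, object@F2,
            object@temporalKernel, object@separableKernel, object@pool) < 1L))
    msg <- c(msg, "all architecture counts must be positive")
  if (object@dropout < 0 || object@dropout >= 1)
    msg <- c(msg, "dropout must lie in [0, 1)")
  if (object@T < object@pool)
    msg <- c(msg, "T must be at least the pooling width")
  if (!object@activation %in% c("elu", "linear"))
    msg <- c(msg, "activation must be elu or linear")
  if (length(msg)) msg else TRUE
})

#' Fitted spatiotemporal CNN
#'
#' A fitted (or freshly initialized) depthwise-separable CNN. The model has
#' one backbone per input modality (one for single-input models, two for
#' dual phase+intensity models) and a shared dense sigmoid head over the
#' concatenated flattened backbone features.
#'
#' @slot configs list of \linkS4class{ModelConfig}, one per backbone.
#' @slot params named list: \code{branches} (per-backbone weights and
#'   batch-norm parameters/running statistics), \code{Wfc}, \code{bfc}.
#' @export
setClass("CnnModel", representation(configs = "list", params = "list"))

setValidity("CnnModel", function(object) {
  if (!length(object@configs)) return("at least one backbone config required")
  if (!all(vapply(object@configs, is, TRUE, class2 = "ModelConfig")))
    return("configs must be ModelConfig objects")
  if (length(object@params$branches) != length(object@configs))
    return("one parameter branch required per config")
  TRUE
})

#' Training configuration
#'
#' @slot maxEpochs maximum passes over the training data.
#' @slot optimizer "adam" or "sgd" (SGD with momentum 0.9).
#' @slot learningRate optimizer step size.
#' @slot weightDecay L2 penalty coefficient applied by the optimizer.
#' @slot earlyStopMetric validation metric monitored for early stopping:
#'   "accuracy", "auroc" (maximized) or "loss" (minimized).
#' @slot patience epochs without improvement before stopping; the weights
#'   of the best validation epoch are restored.
#' @slot batchSize minibatch size.
#' @slot seed integer seed controlling initialization, shuffling, dropout.
#' @export
setClass("TrainConfig", representation(
  maxEpochs = "integer", optimizer = "character", learningRate = "numeric",
  weightDecay = "numeric", earlyStopMetric = "character",
  patience = "integer", batchSize = "integer", seed = "integer"
))

setValidity("TrainConfig", function(object) {
  msg <- character()
  if (object@maxEpochs < 1L) msg <- c(msg, "maxEpochs must be >= 1")
  if (object@patience >= object@maxEpochs && object@maxEpochs > 1L)
    msg <- c(msg, "patience must be smaller than maxEpochs")
  if (!object@optimizer %in% c("adam", "sgd"))
    msg <- c(msg, "optimizer must be adam or sgd")
  if (!object@earlyStopMetric %in% c("accuracy", "auroc", "loss"))
    msg <- c(msg, "earlyStopMetric must be accuracy, auroc or loss")
  if (object@learningRate < 0) msg <- c(msg, "learningRate must be >= 0")
  if (object@batchSize < 1L) msg <- c(msg, "batchSize must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Train/validation/test split specification
#'
#' A 20% held-out test set stratified by response label (and by montage for
#' pooled multi-montage runs), with the remaining 80% partitioned into
#' k cross-validation folds, each fold serving as validation exactly once.
#'
#' @slot testIdx indices of the held-out test trials.
#' @slot folds list of \code{list(train =, val =)} index vectors.
#' @slot strata the factor used for stratification (one value per trial).
#' @export
setClass("SplitSpec", representation(
  testIdx = "integer", folds = "list", strata = "factor"
))

setValidity("SplitSpec", function(object) {
  pool <- sort(unlist(lapply(object@folds, function(f) f$val)))
  msg <- character()
  if (length(intersect(object@testIdx,
                       unlist(lapply(object@folds, unlist)))))
    msg <- c(msg, "test indices must be disjoint from all folds")
  if (any(duplicated(pool)))
    msg <- c(msg, "each pooled trial must be validation exactly once")
  for (f in object@folds)
    if (length(intersect(f$train, f$val)))
      msg <- c(msg, "train and validation overlap within a fold")
  if (length(msg)) msg else TRUE
})

#' One fitted model with its provenance
#'
#' @slot model the fitted \linkS4class{CnnModel}.
#' @slot history data.frame of per-epoch train/validation metrics.
#' @slot bestEpoch epoch whose weights were restored.
#' @slot metrics list with held-out \code{testAccuracy}, \code{testAuroc},
#'   \code{nTest}, \code{nCorrect} and the monitored \code{valMetric}.
#' @slot fold fold index within the cross-validation.
#' @slot seed initialization/shuffling seed of this run.
#' @export
setClass("TrainRun", representation(
  model = "CnnModel", history = "data.frame", bestEpoch = "integer",
  metrics = "list", fold = "integer", seed = "integer"
))

#' Attribution map aligned to the input grid
#'
#' Signed DeepLIFT (Rescale) relevance for one trial or a group average,
#' aligned to the model input's voxel-by-time grid. Positive values push
#' the sigmoid output towards the "right response" direction.
#'
#' @slot relevance numeric C x T matrix of signed relevance.
#' @slot prediction model output for the attributed trial (NA for group
#'   averages of heterogeneous predictions).
#' @slot delta f(trial) - f(reference); the relevance sums to this.
#' @slot group optional group tag (response x confidence).
#' @slot fs sampling rate (Hz) of the time axis.
#' @export
setClass("AttributionMap", representation(
  relevance = "matrix", prediction = "numeric", delta = "numeric",
  group = "character", fs = "numeric"
))

setValidity("AttributionMap", function(object) {
  if (any(!is.finite(object@relevance))) "relevance must be finite" else TRUE
})
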