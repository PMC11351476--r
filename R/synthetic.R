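# Synthetic frequency-domain optical data with the statistical structure
# the decoding pipeline assumes: a hand-lateralized event-related
# deflection over motor cortex buried in 1/f + white noise with a pulse
# artifact, recorded through montages of varying quality.

#' Draw a montage quality specification
#'
#' Samples which ROI voxels are viable (receive at least one
#' quality-passing channel), how many channels map to each viable voxel,
#' and the montage's latency jitter. Deterministic given
#' \code{(cfg@@seed, montageId)}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param montageId montage label "A".."D".
#' @return a \linkS4class{MontageSpec}.
#' @examples
#' makeMontageSpec(simConfig(seed = 7), "B")
#' @export
makeMontageSpec <- function(cfg, montageId = "A") {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  C <- cfg@nVoxels
  withSeed(deriveSeed(cfg@seed, "montage", montageId), {
    drop <- stats::runif(1, cfg@voxelDropoutRange[1], cfg@voxelDropoutRange[2])
    nDrop <- round(drop * C)
    if (nDrop >= C) stop("dropout range leaves no viable voxels")
    mask <- rep(TRUE, C)
    if (nDrop > 0) mask[sample.int(C, nDrop)] <- FALSE
    k <- integer(C)
    kr <- cfg@channelsPerVoxelRange
    k[mask] <- if (kr[1] == kr[2]) kr[1] else
      sample(seq(kr[1], kr[2]), sum(mask), replace = TRUE)
    off <- if (cfg@spatialOffsetMs > 0)
      stats::runif(1, -cfg@spatialOffsetMs, cfg@spatialOffsetMs) else 0
    new("MontageSpec", montageId = montageId, viableVoxelMask = mask,
        channelsPerVoxel = k, latencyOffsetMs = off)
  })
}

# Gaussian bump time course of the planted effect, evaluated at `tMs`
# (ms relative to the response). Latencies may be jittered per montage.
effectTimeCourse <- function(cfg, tMs, latencyOffsetMs = 0) {
  lat <- cfg@effectLatencies + latencyOffsetMs
  rowSums(vapply(lat, function(l)
    exp(-(tMs - l) ^ 2 / (2 * cfg@effectSigmaMs ^ 2)), numeric(length(tMs))))
}

#' Deterministic single-trial effect template
#'
#' The noise-free planted signal: Gaussian bumps at the configured
#' latencies in the right-hemisphere effect voxel (amplitude 1.5 x) and
#' its left-hemisphere mirror (amplitude 1 x), with the sign flipped
#' between right- and left-hand responses (positive for "right"). Voxels
#' that are non-viable in \code{mspec} carry no template.
#'
#' @param label "left" or "right".
#' @param cfg a \linkS4class{SimConfig}.
#' @param mspec optional \linkS4class{MontageSpec}; NULL means all voxels
#'   viable and no latency jitter.
#' @param modality "phase" or "intensity" (intensity is attenuated by
#'   \code{cfg@@intensityEffectScale}).
#' @param tMs sample times (ms relative to the response).
#' @return C x length(tMs) matrix.
#' @export
effectTemplate <- function(label, cfg, mspec = NULL, modality = "phase",
                           tMs = epochTimesMs(cfg@fs)) {
  if (!label %in% c("left", "right")) stop("unknown label: ", label)
  if (!modality %in% c("phase", "intensity"))
    stop("unknown modality: ", modality)
  C <- cfg@nVoxels
  tpl <- matrix(0, C, length(tMs))
  offset <- if (is.null(mspec)) 0 else mspec@latencyOffsetMs
  bump <- effectTimeCourse(cfg, tMs, offset)
  sgn <- if (label == "right") 1 else -1
  amp <- cfg@effectAmplitude *
    (if (modality == "intensity") cfg@intensityEffectScale else 1)
  vRight <- cfg@effectVoxel
  vLeft <- mirrorVoxel(vRight, C)
  viable <- if (is.null(mspec)) rep(TRUE, C) else mspec@viableVoxelMask
  if (viable[vRight]) tpl[vRight, ] <- sgn * 1.5 * amp * bump
  if (viable[vLeft]) tpl[vLeft, ] <- sgn * amp * bump
  tpl
}

# Noise field for a (C x len) recording: white + pink per voxel, scaled
# per voxel by 1/sqrt(channels), plus a shared sinusoidal pulse artifact
# with the supplied phase. Non-viable voxels get single-channel noise.
noiseField <- function(cfg, mspec, len, modality, pulsePhase) {
  C <- cfg@nVoxels
  k <- pmax(mspec@channelsPerVoxel, 1L)
  pinkAmp <- cfg@noiseSd * cfg@pinkScale *
    (if (modality == "intensity") cfg@intensityPinkScale else 1)
  noise <- matrix(stats::rnorm(C * len, sd = cfg@noiseSd), C, len)
  if (pinkAmp > 0)
    noise <- noise + pinkAmp * pinkNoise(C, len, cfg@pinkExponent)
  noise <- noise / sqrt(k)
  if (cfg@pulseAmplitude > 0) {
    tSec <- (seq_len(len) - 1) / cfg@fs
    pulse <- cfg@pulseAmplitude *
      sin(2 * pi * cfg@pulseFreq * tSec + pulsePhase)
    noise <- noise + rep(pulse, each = C)
  }
  noise
}

#' Generate one synthetic single-trial epoch
#'
#' Epoch-level generation (no continuous-recording context): the planted
#' template plus pink noise, white noise and a random-phase pulse
#' artifact, on the model-ready (C, T) grid. Uses the caller's RNG
#' stream; wrap in \code{set.seed()} for reproducibility.
#'
#' @inheritParams effectTemplate
#' @param mspec a \linkS4class{MontageSpec}.
#' @return C x T numeric matrix.
#' @examples
#' cfg <- simConfig(seed = 1)
#' ms <- makeMontageSpec(cfg, "A")
#' set.seed(1); tr <- generateTrial("right", ms, cfg)
#' dim(tr)
#' @export
generateTrial <- function(label, mspec, cfg, modality = "phase") {
  tMs <- epochTimesMs(cfg@fs)
  tpl <- effectTemplate(label, cfg, mspec, modality, tMs)
  phase <- stats::runif(1, 0, 2 * pi)
  tpl + noiseField(cfg, mspec, length(tMs), modality, phase)
}

#' Generate a continuous synthetic block recording
#'
#' One recording block: continuous voxel-level series containing
#' \code{nEvents} manual responses at regular intervals, each followed by
#' the label-dependent planted deflection, on top of the block's noise
#' field and a pulse artifact with a block-specific random phase. The
#' output feeds \code{\link{preprocessBlock}}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param mspec a \linkS4class{MontageSpec}.
#' @param labels response labels, one per event.
#' @param modality "phase" or "intensity".
#' @param spacingSec inter-response interval (s).
#' @param marginSec recording margin before the first and after the last
#'   response (s).
#' @return list with \code{series} (C x N matrix), \code{events}
#'   (response sample indices) and \code{labels}.
#' @export
generateBlockRecording <- function(cfg, mspec, labels, modality = "phase",
                                   spacingSec = 3, marginSec = 3) {
  nEvents <- length(labels)
  fs <- cfg@fs
  N <- ceiling((2 * marginSec + (nEvents - 1) * spacingSec) * fs)
  events <- round(marginSec * fs) + round((seq_len(nEvents) - 1) *
                                            spacingSec * fs)
  phase <- stats::runif(1, 0, 2 * pi)
  series <- noiseField(cfg, mspec, N, modality, phase)
  # plant the deflection around each response
  winMs <- (-round(fs)):(ceiling(0.7 * fs) + round(fs))  # generous window
  for (i in seq_len(nEvents)) {
    idx <- events[i] + winMs
    keep <- idx >= 1 & idx <= N
    tMs <- winMs[keep] / fs * 1000
    tpl <- effectTemplate(labels[i], cfg, mspec, modality, tMs)
    series[, idx[keep]] <- series[, idx[keep]] + tpl
  }
  list(series = series, events = as.integer(events),
       labels = factor(as.character(labels), levels = c("left", "right")))
}

#' Generate a full synthetic subject dataset
#'
#' Runs the whole front half of the pipeline for one subject: for each
#' montage, draws a \linkS4class{MontageSpec}, simulates
#' \code{cfg@@nBlocks} continuous block recordings per modality with
#' balanced left/right manual responses within each block, and passes them
#' through the pre-processing chain (per-block centering, zero-phase
#' band-pass, segmentation, baseline correction, cropping, max-abs
#' scaling). Bitwise deterministic given \code{(cfg, subjectId)}.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param subjectId subject label used for seed derivation and metadata.
#' @param pcfg a \linkS4class{PreprocessConfig}; its \code{fs} should
#'   match \code{cfg@@fs}.
#' @param modalities which modalities to simulate.
#' @return named list (one element per montage letter) of lists with
#'   elements \code{montage} (\linkS4class{MontageSpec}) and one
#'   \linkS4class{TrialSet} per modality.
#' @examples
#' \donttest{
#' cfg <- simConfig(nMontages = 1L, nBlocks = 2L, seed = 3)
#' ds <- generateSubjectDataset(cfg, "S1", modalities = "phase")
#' ds$A$phase
#' }
#' @export
generateSubjectDataset <- function(cfg, subjectId = "S1",
                                   pcfg = preprocessConfig(fs = cfg@fs),
                                   modalities = c("phase", "intensity")) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  nManual <- round(cfg@trialsPerBlock * cfg@manualFraction)
  out <- list()
  for (m in LETTERS[seq_len(cfg@nMontages)]) {
    mspec <- makeMontageSpec(cfg, m)
    entry <- list(montage = mspec)
    for (mod in modalities) {
      epochs <- vector("list", cfg@nBlocks)
      labs <- vector("list", cfg@nBlocks)
      blocks <- vector("list", cfg@nBlocks)
      for (b in seq_len(cfg@nBlocks)) {
        labels <- withSeed(
          deriveSeed(cfg@seed, subjectId, m, "labels", b),
          sample(rep(c("left", "right"), length.out = nManual)))
        rec <- withSeed(
          deriveSeed(cfg@seed, subjectId, m, mod, b),
          generateBlockRecording(cfg, mspec, labels, mod))
        ep <- preprocessBlock(rec$series, rec$events, pcfg,
                              labels = rec$labels, blockIndex = b)
        epochs[[b]] <- ep$epochs
        labs[[b]] <- as.character(ep$labels)
        blocks[[b]] <- rep(b, length(ep$labels))
      }
      epochs <- do.call(c, epochs)
      arr <- array(unlist(epochs),
                   c(dim(epochs[[1L]]), length(epochs)))
      entry[[mod]] <- trialSet(arr, unlist(labs), unlist(blocks),
                               modality = mod, subjectId = subjectId,
                               montageId = m, fs = cfg@fs)
    }
    out[[m]] <- entry
  }
  out
}
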