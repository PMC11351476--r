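# Fast-optical-signal pre-processing: continuous block recordings in,
# model-ready scaled single-trial matrices out.

#' Correct phase wrapping
#'
#' Removes modulation-cycle wraps from a phase series: any
#' successive-sample jump exceeding half the wrap period in magnitude is
#' cancelled by adding the appropriate integer multiple of the period to
#' the remainder of the series.
#'
#' @param series numeric phase series.
#' @param wrapPeriod phase units per modulation cycle.
#' @return unwrapped series of the same length.
#' @examples
#' x <- c(10, 170, -170, -100)      # one wrap of a 360-unit cycle
#' unwrapPhase(x, 360)
#' @export
unwrapPhase <- function(series, wrapPeriod) {
  stopifnot(wrapPeriod > 0)
  if (any(!is.finite(series))) stop("series must be finite")
  if (length(series) < 2L) return(series)
  jumps <- round(diff(series) / wrapPeriod)
  series - c(0, cumsum(jumps)) * wrapPeriod
}

#' Regress out a pulse artifact
#'
#' Removes the least-squares projection of a series onto a pulse
#' reference waveform and its quadrature (90-degree shifted copy,
#' computed via the analytic signal), leaving a residual orthogonal to
#' both regressors. This accommodates arbitrary pulse phase.
#'
#' @param series numeric series.
#' @param pulseReference pulse waveform of the same length.
#' @return residual series.
#' @export
regressPulse <- function(series, pulseReference) {
  stopifnot(length(series) == length(pulseReference))
  if (stats::sd(pulseReference) == 0)
    stop("pulse reference has zero variance")
  n <- length(series)
  # quadrature via the analytic signal
  H <- stats::fft(pulseReference)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  quad <- Im(stats::fft(H * h, inverse = TRUE) / n)
  X <- cbind(1, pulseReference, quad)
  stats::lm.fit(X, series)$residuals
}

#' Filter channels by quality-control criteria
#'
#' Keeps a channel iff its source-detector distance lies inside the
#' inclusive interval \code{cfg@@qcDistanceCm}, its phase standard
#' deviation is strictly below \code{cfg@@qcPhaseSdMax}, and its mean raw
#' AC value is strictly above \code{cfg@@qcAcMinMv}. Order is preserved;
#' an empty result is allowed.
#'
#' @param channels list of channel records; each a list with numeric
#'   fields \code{distance} (cm), \code{phaseSd}, \code{meanAc} (mV), and
#'   optionally \code{series} and \code{voxelTargets}.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return the kept sublist.
#' @export
qcChannels <- function(channels, cfg = preprocessConfig()) {
  keep <- vapply(channels, function(ch) {
    ch$distance >= cfg@qcDistanceCm[1] && ch$distance <= cfg@qcDistanceCm[2] &&
      ch$phaseSd < cfg@qcPhaseSdMax && ch$meanAc > cfg@qcAcMinMv
  }, logical(1))
  channels[keep]
}

#' Project channel series onto the voxel grid
#'
#' Each viable voxel becomes the unweighted mean of all channel series
#' mapping to it (a declared simplification of diffusion-path weighted
#' reconstruction). Voxels with no contributing channel are returned as
#' all-zero rows and reported in the \code{viable} attribute.
#'
#' @param channels list of channel records with \code{series} (numeric,
#'   equal lengths) and \code{voxelTargets} (integer voxel indices).
#' @param nVoxels number of rows of the output grid.
#' @return nVoxels x samples matrix with attribute \code{viable}.
#' @export
projectVoxels <- function(channels, nVoxels) {
  if (!length(channels)) stop("no channels to project")
  len <- length(channels[[1L]]$series)
  acc <- matrix(0, nVoxels, len)
  cnt <- integer(nVoxels)
  for (ch in channels) {
    stopifnot(length(ch$series) == len)
    for (v in ch$voxelTargets) {
      if (v < 1L || v > nVoxels) stop("voxel target outside grid")
      acc[v, ] <- acc[v, ] + ch$series
      cnt[v] <- cnt[v] + 1L
    }
  }
  viable <- cnt > 0L
  acc[viable, ] <- acc[viable, , drop = FALSE] / cnt[viable]
  structure(acc, viable = viable)
}

# Zero-phase 4th-order Butterworth band-pass of each row of a (C x N)
# matrix: the filter's squared magnitude response (the forward-backward
# response) is applied in the frequency domain, which is exactly
# zero-phase and free of the edge transients of sequential forward and
# reverse passes. Rows are extended by odd reflection over several time
# constants of the low cut-off to suppress circular wrap-around.
bandPass <- function(x, band, fs) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  N <- ncol(x)
  pad <- min(N - 1L, ceiling(3 * fs / band[1L]))
  ext <- cbind(2 * x[, 1L] - x[, (pad + 1L):2L, drop = FALSE], x,
               2 * x[, N] - x[, (N - 1L):(N - pad), drop = FALSE])
  M <- ncol(ext)
  w <- 2 * pi * (seq_len(M) - 1L) / M
  E <- exp(-1i * outer(w, seq_along(bf$b) - 1L))
  H2 <- Mod((E %*% bf$b) / (E %*% bf$a)) ^ 2
  X <- t(stats::mvfft(t(ext)))
  Y <- Re(t(stats::mvfft(t(X * rep(H2, each = nrow(x))),
                         inverse = TRUE))) / M
  Y[, pad + seq_len(N), drop = FALSE]
}

#' Segment a filtered block into baseline-corrected epochs
#'
#' Cuts a window of \code{baseline + crop} samples around each event,
#' subtracts the per-voxel mean of the baseline window (the
#' \code{cfg@@baselineMs} period immediately preceding and including the
#' response sample), and returns the uncropped epochs. Events too close
#' to the block edge are skipped with a warning.
#'
#' @param series C x N matrix (already centred and filtered).
#' @param events response sample indices.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return list with \code{epochs} (list of C x (baseline+post) matrices,
#'   response sample at index \code{nBaseline}), \code{kept} (logical per
#'   event), \code{nBaseline} (baseline window length in samples).
#' @export
segmentEpochs <- function(series, events, cfg = preprocessConfig()) {
  nB <- round(cfg@baselineMs / 1000 * cfg@fs)      # 39 at defaults
  nPost <- epochHalf(cfg@fs, cfg@cropMs)           # 28 at defaults
  N <- ncol(series)
  kept <- logical(length(events))
  epochs <- list()
  for (i in seq_along(events)) {
    ev <- events[i]
    lo <- ev - nB + 1L
    hi <- ev + nPost
    if (lo < 1L || hi > N) {
      warning("event ", i, " too close to block edge; epoch skipped")
      next
    }
    ep <- series[, lo:hi, drop = FALSE]
    base <- rowMeans(ep[, seq_len(nB), drop = FALSE])
    epochs[[length(epochs) + 1L]] <- ep - base
    kept[i] <- TRUE
  }
  list(epochs = epochs, kept = kept, nBaseline = nB)
}

#' Crop a baseline-corrected epoch to the model window
#'
#' Retains \code{epochHalf(fs, cropMs)} samples before and after the
#' response sample (56 samples total at defaults).
#'
#' @param epoch C x (baseline+post) matrix from \code{\link{segmentEpochs}}.
#' @param nBaseline index of the response sample within \code{epoch}.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return C x T matrix with T = \code{epochLength(cfg@@fs, cfg@@cropMs)}.
#' @export
cropEpoch <- function(epoch, nBaseline, cfg = preprocessConfig()) {
  nHalf <- epochHalf(cfg@fs, cfg@cropMs)
  idx <- (nBaseline - nHalf + 1L):(nBaseline + nHalf)
  epoch[, idx, drop = FALSE]
}

#' Scale an epoch by its global maximum absolute value
#'
#' Divides the whole C x T matrix by its single largest absolute entry so
#' the result has max |value| = 1; an all-zero epoch is returned
#' unchanged. Ratios between entries and the argmax location are
#' preserved.
#'
#' @param epoch numeric matrix.
#' @return scaled matrix.
#' @export
scaleMaxAbs <- function(epoch) {
  if (any(!is.finite(epoch))) stop("epoch must be finite")
  m <- max(abs(epoch))
  if (m == 0) epoch else epoch / m
}

#' Pre-process one continuous block recording
#'
#' The full chain in order: per-block mean centring (per voxel), zero-phase
#' Butterworth band-pass, segmentation at each response, per-voxel
#' baseline correction over the pre-response window, cropping to the
#' model window, and (optionally) per-trial max-abs scaling.
#'
#' @param series C x N continuous voxel series for one block.
#' @param events response sample indices within the block.
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @param labels optional per-event labels, subset to the kept epochs.
#' @param blockIndex block number stored alongside the epochs.
#' @param scale apply \code{\link{scaleMaxAbs}} per epoch.
#' @return list with \code{epochs} (list of C x T matrices),
#'   \code{labels}, \code{blockIndex}.
#' @examples
#' cfg <- simConfig(seed = 1)
#' ms <- makeMontageSpec(cfg, "A")
#' set.seed(1)
#' rec <- generateBlockRecording(cfg, ms, c("left", "right"))
#' pp <- preprocessBlock(rec$series, rec$events, labels = rec$labels)
#' dim(pp$epochs[[1]])
#' @export
preprocessBlock <- function(series, events, cfg = preprocessConfig(),
                            labels = NULL, blockIndex = 1L, scale = TRUE) {
  stopifnot(is.matrix(series))
  centred <- series - rowMeans(series)
  filtered <- bandPass(centred, cfg@band, cfg@fs)
  seg <- segmentEpochs(filtered, events, cfg)
  epochs <- lapply(seg$epochs, cropEpoch, nBaseline = seg$nBaseline,
                   cfg = cfg)
  if (scale) epochs <- lapply(epochs, scaleMaxAbs)
  if (!is.null(labels)) labels <- labels[seg$kept]
  list(epochs = epochs, labels = labels, blockIndex = as.integer(blockIndex))
}

#' Summarize channel quality control as a report table
#'
#' @param channels list of channel records (see \code{\link{qcChannels}}).
#' @param cfg a \linkS4class{PreprocessConfig}.
#' @return data.frame with one row per channel: metrics and kept flag.
#' @export
qcReport <- function(channels, cfg = preprocessConfig()) {
  kept <- vapply(qcChannelsMask(channels, cfg), identity, logical(1))
  data.frame(
    channel = seq_along(channels),
    distance = vapply(channels, `[[`, numeric(1), "distance"),
    phaseSd = vapply(channels, `[[`, numeric(1), "phaseSd"),
    meanAc = vapply(channels, `[[`, numeric(1), "meanAc"),
    kept = kept)
}

qcChannelsMask <- function(channels, cfg) {
  lapply(channels, function(ch)
    ch$distance >= cfg@qcDistanceCm[1] && ch$distance <= cfg@qcDistanceCm[2] &&
      ch$phaseSd < cfg@qcPhaseSdMax && ch$meanAc > cfg@qcAcMinMv)
}
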