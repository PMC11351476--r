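# DeepLIFT (Rescale rule) input relevance, confidence grouping, and
# averaged spatiotemporal / spatial-slice heatmaps.
#
# Every layer of the network is either linear in its input (convolutions,
# batch normalization in inference mode, average pooling, the dense
# head) or an elementwise nonlinearity (ELU, sigmoid). Multipliers are
# therefore the layer weights for linear layers and the Rescale ratio
# delta-out / delta-in for nonlinearities (falling back to the local
# gradient when delta-in vanishes), which composes into relevance that
# satisfies summation-to-delta exactly up to floating-point error.

rescaleMult <- function(xNew, xRef, f, g, tol = 1e-7) {
  dx <- xNew - xRef
  m <- ifelse(abs(dx) > tol, (f(xNew) - f(xRef)) / dx, g(xNew))
  m
}

branchMultipliers <- function(pb, cfg, cacheX, cacheR, mFeat) {
  C <- cfg@C; Tlen <- cfg@T
  K1 <- cfg@temporalKernel; K2 <- cfg@separableKernel
  F1 <- cfg@F1; D <- cfg@D; F2 <- cfg@F2; DF1 <- D * F1
  pool <- cfg@pool; Tp <- Tlen %/% pool
  act <- activationFun(cfg)
  eps <- 1e-5

  mQ <- array(mFeat, c(F2, Tp, 1L))
  mA3 <- array(0, c(F2, Tlen, 1L))
  for (q in seq_len(Tp)) for (i in seq_len(pool))
    mA3[, (q - 1L) * pool + i, ] <- mQ[, q, ] / pool
  mY3 <- matrix(mA3, F2, Tlen) *
    rescaleMult(matrix(cacheX$b3$y, F2, Tlen),
                matrix(cacheR$b3$y, F2, Tlen), act$f, act$g)
  mP <- pb$bn3$gamma / sqrt(pb$bn3$rv + eps) * mY3
  mS <- crossprod(pb$Wp, mP)
  mSa <- array(mS, c(DF1, Tlen, 1L))
  mZp <- array(0, c(DF1, Tlen + K2 - 1L, 1L))
  for (k in seq_len(K2))
    mZp[, k:(k + Tlen - 1L), ] <- mZp[, k:(k + Tlen - 1L), , drop = FALSE] +
      pb$Wd[, k] * mSa
  padL2 <- samePad(K2)[1L]
  mA2 <- matrix(mZp[, padL2 + seq_len(Tlen), , drop = FALSE], DF1, Tlen)
  mY2 <- mA2 * rescaleMult(matrix(cacheX$b2$y, DF1, Tlen),
                           matrix(cacheR$b2$y, DF1, Tlen), act$f, act$g)
  mZ <- pb$bn2$gamma / sqrt(pb$bn2$rv + eps) * mY2
  mY1 <- matrix(0, F1, C * Tlen)
  for (f in seq_len(F1)) {
    rows <- ((f - 1L) * D + 1L):(f * D)
    mY1[f, ] <- pb$Ws[, rows, drop = FALSE] %*% mZ[rows, , drop = FALSE]
  }
  mH1 <- pb$bn1$gamma / sqrt(pb$bn1$rv + eps) * mY1
  mH1a <- array(mH1, c(F1, C, Tlen, 1L))
  padL1 <- samePad(K1)[1L]
  mXp <- array(0, c(C, Tlen + K1 - 1L, 1L))
  for (k in seq_len(K1)) {
    contrib <- colSums(mH1a * pb$Wt[, k], dims = 1L)
    mXp[, k:(k + Tlen - 1L), ] <- mXp[, k:(k + Tlen - 1L), , drop = FALSE] +
      contrib
  }
  matrix(mXp[, padL1 + seq_len(Tlen), , drop = FALSE], C, Tlen)
}

#' DeepLIFT (Rescale rule) input relevance
#'
#' Propagates multipliers from the sigmoid output back to the input grid
#' against a reference input (default all-zeros, the natural rest point
#' of the scaled, baseline-corrected signal), assigning each voxel and
#' time step a signed relevance. Positive relevance supports the
#' right-response direction of the output. The relevance satisfies
#' summation-to-delta: it sums to f(trial) - f(reference).
#'
#' @param model a \linkS4class{CnnModel} (evaluation mode is implied).
#' @param trial C x T matrix, or a list with one matrix per backbone for
#'   dual-input models.
#' @param reference baseline input of the same shape; NULL means zeros.
#' @return an \linkS4class{AttributionMap} (for dual-input models the
#'   relevance of the branches is stacked by rows).
#' @export
deepliftRescale <- function(model, trial, reference = NULL) {
  trials <- asBranchList(model, trial)
  trials <- lapply(trials, function(x) if (is.matrix(x)) x else
    matrix(x, dim(x)[1L], dim(x)[2L]))
  refs <- if (is.null(reference))
    lapply(trials, function(x) x * 0) else
      lapply(asBranchList(model, reference), function(x)
        if (is.matrix(x)) x else matrix(x, dim(x)[1L], dim(x)[2L]))
  for (i in seq_along(trials))
    if (!identical(dim(trials[[i]]), dim(refs[[i]])))
      stop("trial and reference shapes differ")

  fwX <- cnnForward(model, if (length(trials) == 1L) trials[[1L]] else
    trials, training = FALSE, keepCache = TRUE)
  fwR <- cnnForward(model, if (length(refs) == 1L) refs[[1L]] else refs,
                    training = FALSE, keepCache = TRUE)
  mZ <- rescaleMult(fwX$z, fwR$z, stats::plogis,
                    function(z) stats::plogis(z) * (1 - stats::plogis(z)),
                    tol = 1e-9)
  mFeatAll <- drop(mZ) * as.numeric(model@params$Wfc)
  offsets <- cumsum(c(0L, vapply(model@configs, featureLength, integer(1))))
  rel <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    rows <- (offsets[i] + 1L):offsets[i + 1L]
    mX <- branchMultipliers(model@params$branches[[i]], model@configs[[i]],
                            fwX$caches[[i]], fwR$caches[[i]],
                            mFeatAll[rows])
    rel[[i]] <- mX * (trials[[i]] - refs[[i]])
  }
  relevance <- do.call(rbind, rel)
  new("AttributionMap", relevance = relevance,
      prediction = unname(fwX$prob), delta = unname(fwX$prob - fwR$prob),
      group = character(), fs = 39.0625)
}

#' Group trials by response type and prediction confidence
#'
#' High confidence means a prediction below \code{lowConf} or above
#' \code{highConf}; predictions between the bounds (inclusive) are low
#' confidence. Crossed with the response label this yields four groups;
#' every trial falls in exactly one.
#'
#' @param predictions numeric vector in [0, 1].
#' @param labels per-trial response labels.
#' @param lowConf,highConf confidence bounds.
#' @return factor with levels left.high, left.low, right.high, right.low.
#' @examples
#' groupByConfidence(c(0.15, 0.5, 0.9), c("left", "left", "right"))
#' @export
groupByConfidence <- function(predictions, labels, lowConf = 0.20,
                              highConf = 0.80) {
  stopifnot(all(predictions >= 0 & predictions <= 1),
            lowConf > 0, highConf < 1, lowConf < highConf)
  labels <- factor(as.character(labels), levels = c("left", "right"))
  confidence <- ifelse(predictions < lowConf | predictions > highConf,
                       "high", "low")
  factor(paste(as.character(labels), confidence, sep = "."),
         levels = c("left.high", "left.low", "right.high", "right.low"))
}

#' Average a group of attribution maps
#'
#' Element-wise mean over maps of identical shape. An empty group yields
#' NULL (an explicit empty result).
#'
#' @param maps list of \linkS4class{AttributionMap}s.
#' @param group optional group tag stored on the result.
#' @return an \linkS4class{AttributionMap} or NULL.
#' @export
meanHeatmap <- function(maps, group = character()) {
  if (!length(maps)) return(NULL)
  rel <- Reduce(`+`, lapply(maps, relevance)) / length(maps)
  preds <- vapply(maps, function(m) m@prediction, numeric(1))
  new("AttributionMap", relevance = rel,
      prediction = if (length(unique(preds)) == 1L) preds[1L] else NA_real_,
      delta = mean(vapply(maps, function(m) m@delta, numeric(1))),
      group = as.character(group), fs = maps[[1L]]@fs)
}

#' Spatial slice of an attribution map at a latency
#'
#' Nearest-sample lookup of the relevance column at \code{tMs}
#' milliseconds after the response, reshaped to the two-hemisphere ROI
#' grids.
#'
#' @param map an \linkS4class{AttributionMap} whose row count matches the
#'   voxel grid.
#' @param tMs latency (ms relative to the response).
#' @param cols columns per hemisphere grid.
#' @return list with \code{left} and \code{right} (rows x cols matrices),
#'   plus the \code{sample} index used.
#' @export
timeSlice <- function(map, tMs, cols = 7L) {
  rel <- relevance(map)
  idx <- timeToSample(tMs, map@fs)
  if (idx > ncol(rel)) stop("latency outside the epoch window")
  grid <- voxelGrid(nrow(rel), cols)
  v <- rel[, idx]
  half <- nrow(rel) %/% 2L
  rows <- half %/% cols
  list(left = matrix(v[seq_len(half)], rows, cols, byrow = TRUE),
       right = matrix(v[half + seq_len(half)], rows, cols, byrow = TRUE),
       sample = idx)
}

#' Locate the peak of an attribution map
#'
#' The (voxel, sample) coordinate of the largest absolute relevance;
#' used to check that attribution localizes a planted effect.
#'
#' @param map an \linkS4class{AttributionMap}.
#' @return list with \code{voxel}, \code{sample}, \code{value}.
#' @export
peakRelevance <- function(map) {
  rel <- relevance(map)
  i <- which.max(abs(rel))
  voxel <- ((i - 1L) %% nrow(rel)) + 1L
  sample <- ((i - 1L) %/% nrow(rel)) + 1L
  list(voxel = voxel, sample = sample, value = rel[i])
}
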