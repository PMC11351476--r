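# Epoch geometry shared by the generator, pre-processing and attribution.
# The retained epoch has round(cropMs/1000 * fs) samples on each side of
# the response sample; at 39.0625 Hz and 716 ms this is 28 + 28 = 56, with
# the response at sample index `epochZeroIndex`.

epochHalf <- function(fs = 39.0625, cropMs = 716) round(cropMs / 1000 * fs)

#' Epoch length in samples
#'
#' Number of samples of a model-ready epoch: \code{round(cropMs/1000*fs)}
#' samples before and after the response. 56 at the default 39.0625 Hz and
#' 716 ms half-window.
#'
#' @param fs sampling rate (Hz).
#' @param cropMs half-window around the response (ms).
#' @return integer number of samples.
#' @export
epochLength <- function(fs = 39.0625, cropMs = 716) 2L * epochHalf(fs, cropMs)

#' Index of the response sample within an epoch
#' @inheritParams epochLength
#' @return 1-based sample index corresponding to 0 ms (the response).
#' @export
epochZeroIndex <- function(fs = 39.0625, cropMs = 716) epochHalf(fs, cropMs)

#' Epoch sample times in ms relative to the response
#' @inheritParams epochLength
#' @return numeric vector of length \code{epochLength(fs, cropMs)}.
#' @export
epochTimesMs <- function(fs = 39.0625, cropMs = 716) {
  Tlen <- epochLength(fs, cropMs)
  (seq_len(Tlen) - epochZeroIndex(fs, cropMs)) / fs * 1000
}

#' Map a post-response latency to its epoch sample index
#'
#' Nearest-sample lookup under the epoch convention: 0 ms maps to the
#' response sample, so 179 ms at 39.0625 Hz maps to sample
#' 28 + round(0.179 * 39.0625) = 35.
#'
#' @param tMs latency in ms relative to the response (may be negative).
#' @inheritParams epochLength
#' @return 1-based sample index.
#' @export
timeToSample <- function(tMs, fs = 39.0625, cropMs = 716) {
  idx <- epochZeroIndex(fs, cropMs) + round(tMs / 1000 * fs)
  Tlen <- epochLength(fs, cropMs)
  if (any(idx < 1 | idx > Tlen)) stop("latency outside the epoch window")
  as.integer(idx)
}

# Deterministic derived seeds: mix a base seed with integer/character ids
# so that independent streams (subject, montage, block, fold, init) never
# collide while staying below 2^31.
deriveSeed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed %% 2147483647L)
  for (p in parts) {
    codes <- if (is.character(p)) utf8ToInt(paste(p, collapse = "")) else
      as.integer(p)
    for (k in codes) h <- (h * 69069 + as.double(k) + 1) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's RNG stream afterwards.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

elu <- function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1)
eluGrad <- function(x) ifelse(x > 0, 1, exp(pmin(x, 0)))

#' ROI voxel grid geometry
#'
#' Layout of the flattened two-hemisphere region-of-interest grid. Each
#' hemisphere is a rows x cols grid (row-major flattening); the left
#' hemisphere occupies indices 1..C/2 and the right hemisphere C/2+1..C.
#' With the default C = 42 each hemisphere is 3 rows x 7 columns,
#' matching a 6 x 7 cm ROI at 2 x 1 cm voxel spacing.
#'
#' @param C total flattened voxel count (even).
#' @param cols columns per hemisphere grid.
#' @return data.frame with columns \code{index}, \code{hemisphere}
#'   ("left"/"right"), \code{row}, \code{col}.
#' @export
voxelGrid <- function(C = 42L, cols = 7L) {
  half <- C %/% 2L
  if (half %% cols != 0L) stop("C/2 must be divisible by cols")
  rows <- half %/% cols
  one <- data.frame(row = rep(seq_len(rows), each = cols),
                    col = rep(seq_len(cols), rows))
  data.frame(index = seq_len(C),
             hemisphere = rep(c("left", "right"), each = half),
             rbind(one, one))
}

#' Mirror voxel in the opposite hemisphere
#' @param index flattened voxel index.
#' @param C total voxel count.
#' @return flattened index of the homotopic voxel.
#' @export
mirrorVoxel <- function(index, C = 42L) {
  half <- C %/% 2L
  ifelse(index > half, index - half, index + half)
}

# 1/f^alpha noise via spectral shaping of white noise; returns an n x len
# matrix of independent rows, each scaled to unit standard deviation.
pinkNoise <- function(n, len, alpha = 1) {
  if (alpha == 0) return(matrix(stats::rnorm(n * len), n, len))
  f <- pmin(seq_len(len) - 1, len + 1 - seq_len(len))
  f[1] <- 1
  shape <- 1 / (f ^ (alpha / 2))
  w <- matrix(stats::rnorm(n * len), n, len)
  W <- t(stats::mvfft(t(w)))
  X <- Re(t(stats::mvfft(t(W * rep(shape, each = n)), inverse = TRUE))) / len
  sds <- sqrt(rowMeans(X ^ 2) - rowMeans(X) ^ 2)
  sds[sds == 0] <- 1
  X / sds
}
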