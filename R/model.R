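# Compact depthwise-separable spatiotemporal CNN, authored directly in
# vectorised R. Layer order: temporal convolution (F1 filters, (1, K)),
# batch-norm, depthwise spatial convolution ((C, 1), D filters per
# temporal filter, max-norm 1), batch-norm, ELU, dropout, separable
# convolution ((1, K) depthwise + (1, 1) pointwise to F2), batch-norm,
# ELU, average pooling (1, pool), dropout, flatten, dense sigmoid head
# (max-norm 0.25). Convolutions carry no bias; the dense layer does.
#
# Batch layout throughout: inputs are (C, T, n) arrays; the temporal-conv
# feature map lives as an (F1, C*T*n) matrix whose rows are channels, so
# batch-norm is a per-row operation and convolutions are single GEMMs.

samePad <- function(K) {
  padL <- (K - 1L) %/% 2L
  c(padL, K - 1L - padL)                     # (9, 10) for K = 20
}

featureLength <- function(cfg) cfg@F2 * (cfg@T %/% cfg@pool)

glorot <- function(nr, nc, fanIn, fanOut) {
  l <- sqrt(6 / (fanIn + fanOut))
  matrix(stats::runif(nr * nc, -l, l), nr, nc)
}

newBn <- function(ch) list(gamma = rep(1, ch), beta = rep(0, ch),
                           rm = rep(0, ch), rv = rep(1, ch))

initBranch <- function(cfg) {
  DF1 <- cfg@D * cfg@F1
  list(
    Wt = glorot(cfg@F1, cfg@temporalKernel, cfg@temporalKernel,
                cfg@temporalKernel),
    bn1 = newBn(cfg@F1),
    Ws = glorot(cfg@C, DF1, cfg@C, cfg@D),
    bn2 = newBn(DF1),
    Wd = glorot(DF1, cfg@separableKernel, cfg@separableKernel,
                cfg@separableKernel),
    Wp = glorot(cfg@F2, DF1, DF1, cfg@F2),
    bn3 = newBn(cfg@F2))
}

#' Build the depthwise-separable CNN
#'
#' Constructs a single-input network with freshly initialized
#' (Glorot-uniform) weights, already satisfying the max-norm constraints.
#'
#' @param cfg a \linkS4class{ModelConfig}.
#' @param seed initialization seed.
#' @return a \linkS4class{CnnModel}.
#' @examples
#' m <- buildNetwork(modelConfig(F1 = 4L, D = 1L, F2 = 8L), seed = 1)
#' nTrainable(m)
#' @export
buildNetwork <- function(cfg, seed = 1L) {
  validObject(cfg)
  if (cfg@C < 1L || cfg@T < cfg@temporalKernel %/% 2L)
    stop("input smaller than kernel requirements")
  withSeed(seed, {
    L <- featureLength(cfg)
    params <- list(branches = list(initBranch(cfg)),
                   Wfc = glorot(1L, L, L, 1L), bfc = 0)
    constrainWeights(new("CnnModel", configs = list(cfg), params = params))
  })
}

#' Build the dual-input (phase + intensity) network
#'
#' Two parallel backbones (everything before the dense layer), one per
#' modality; their flattened features are concatenated and passed through
#' a single dense sigmoid head with max-norm 0.25.
#'
#' @param cfgPhase,cfgIntensity per-branch \linkS4class{ModelConfig}s;
#'   their \code{T} must match.
#' @param seed initialization seed.
#' @return a \linkS4class{CnnModel} with two backbones.
#' @export
buildDual <- function(cfgPhase, cfgIntensity, seed = 1L) {
  validObject(cfgPhase); validObject(cfgIntensity)
  if (cfgPhase@T != cfgIntensity@T)
    stop("mismatched T between modalities")
  withSeed(seed, {
    L <- featureLength(cfgPhase) + featureLength(cfgIntensity)
    params <- list(branches = list(initBranch(cfgPhase),
                                   initBranch(cfgIntensity)),
                   Wfc = glorot(1L, L, L, 1L), bfc = 0)
    constrainWeights(new("CnnModel",
                         configs = list(cfgPhase, cfgIntensity),
                         params = params))
  })
}

activationFun <- function(cfg) if (cfg@activation == "linear")
  list(f = identity, g = function(x) rep(1, length(x))) else
  list(f = elu, g = eluGrad)

bnForward <- function(x, bn, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    m <- ncol(x)
    mu <- rowMeans(x)
    v <- rowMeans(x ^ 2) - mu ^ 2
    v <- pmax(v, 0)
    istd <- 1 / sqrt(v + eps)
    xhat <- (x - mu) * istd
    bn$rm <- (1 - momentum) * bn$rm + momentum * mu
    bn$rv <- (1 - momentum) * bn$rv + momentum * v * m / max(m - 1, 1)
    list(y = bn$gamma * xhat + bn$beta, xhat = xhat, istd = istd, bn = bn)
  } else {
    scale <- bn$gamma / sqrt(bn$rv + eps)
    list(y = scale * (x - bn$rm) + bn$beta, scale = scale, bn = bn)
  }
}

bnBackward <- function(dy, cache, gamma) {
  dgamma <- rowSums(dy * cache$xhat)
  dbeta <- rowSums(dy)
  dx <- gamma * cache$istd *
    (dy - rowMeans(dy) - cache$xhat * rowMeans(dy * cache$xhat))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

# shift-and-accumulate temporal convolution along dim 2 of a (ch, T, n)
# array, with per-channel kernels W (ch x K) or shared kernels.
padTime <- function(x, K) {
  d <- dim(x)
  padL <- samePad(K)[1L]
  out <- array(0, c(d[1L], d[2L] + K - 1L, d[3L]))
  out[, padL + seq_len(d[2L]), ] <- x
  out
}

# Forward pass of one backbone. X: (C, T, n). Returns flattened features
# (L x n) plus caches for the backward pass / attribution.
branchForward <- function(pb, cfg, X, training = FALSE, keepCache = FALSE) {
  C <- cfg@C; Tlen <- cfg@T; n <- dim(X)[3L]
  K1 <- cfg@temporalKernel; K2 <- cfg@separableKernel
  F1 <- cfg@F1; D <- cfg@D; F2 <- cfg@F2; DF1 <- D * F1
  pool <- cfg@pool; Tp <- Tlen %/% pool
  act <- activationFun(cfg)
  if (dim(X)[1L] != C || dim(X)[2L] != Tlen)
    stop("trial shape does not match the model config")
  Tn <- Tlen * n; CTn <- C * Tn

  Xp <- padTime(X, K1)
  Xcol <- matrix(0, K1, CTn)
  for (k in seq_len(K1)) Xcol[k, ] <- Xp[, k:(k + Tlen - 1L), ]
  H1 <- pb$Wt %*% Xcol                                  # (F1, CTn)
  b1 <- bnForward(H1, pb$bn1, training)
  Y1 <- b1$y

  Z <- matrix(0, DF1, Tn)
  for (f in seq_len(F1)) {
    rows <- ((f - 1L) * D + 1L):(f * D)
    Z[rows, ] <- crossprod(pb$Ws[, rows, drop = FALSE],
                           matrix(Y1[f, ], C, Tn))
  }
  b2 <- bnForward(Z, pb$bn2, training)
  A2 <- act$f(b2$y)
  if (training && cfg@dropout > 0) {
    M2 <- matrix(stats::runif(length(A2)) >= cfg@dropout,
                 nrow(A2), ncol(A2)) / (1 - cfg@dropout)
    A2d <- A2 * M2
  } else { M2 <- NULL; A2d <- A2 }

  Zp <- padTime(array(A2d, c(DF1, Tlen, n)), K2)
  S <- array(0, c(DF1, Tlen, n))
  for (k in seq_len(K2))
    S <- S + pb$Wd[, k] * Zp[, k:(k + Tlen - 1L), , drop = FALSE]
  Sm <- matrix(S, DF1, Tn)
  P <- pb$Wp %*% Sm                                     # (F2, Tn)
  b3 <- bnForward(P, pb$bn3, training)
  A3 <- act$f(b3$y)

  A3a <- array(A3, c(F2, Tlen, n))
  Q <- array(0, c(F2, Tp, n))
  for (q in seq_len(Tp)) {
    sl <- A3a[, (q - 1L) * pool + seq_len(pool), , drop = FALSE]
    Q[, q, ] <- colSums(aperm(sl, c(2L, 1L, 3L))) / pool
  }
  if (training && cfg@dropout > 0) {
    M4 <- array(stats::runif(length(Q)) >= cfg@dropout,
                dim(Q)) / (1 - cfg@dropout)
    Qd <- Q * M4
  } else { M4 <- NULL; Qd <- Q }
  feat <- matrix(Qd, F2 * Tp, n)

  cache <- NULL
  if (keepCache)
    cache <- list(X = X, Xcol = Xcol, H1 = H1, b1 = b1, Y1 = Y1, Z = Z,
                  b2 = b2, A2d = A2d, M2 = M2, Zp = Zp, Sm = Sm, b3 = b3,
                  A3 = A3, M4 = M4, n = n,
                  shapes = list(conv = c(F1, C, Tlen),
                                depthwise = c(DF1, 1L, Tlen),
                                separable = c(F2, 1L, Tlen),
                                pool = c(F2, 1L, Tp),
                                flatten = F2 * Tp))
  list(feat = feat, cache = cache, pb = pb)
}

# Backward pass of one backbone given d(feat). Returns gradients and,
# unused by the optimizer but needed for completeness checks, dX.
branchBackward <- function(pb, cfg, cache, dFeat, wantDx = FALSE) {
  C <- cfg@C; Tlen <- cfg@T; n <- cache$n
  K1 <- cfg@temporalKernel; K2 <- cfg@separableKernel
  F1 <- cfg@F1; D <- cfg@D; F2 <- cfg@F2; DF1 <- D * F1
  pool <- cfg@pool; Tp <- Tlen %/% pool
  act <- activationFun(cfg)
  Tn <- Tlen * n

  dQ <- array(dFeat, c(F2, Tp, n))
  if (!is.null(cache$M4)) dQ <- dQ * cache$M4
  dA3a <- array(0, c(F2, Tlen, n))
  for (q in seq_len(Tp)) for (i in seq_len(pool))
    dA3a[, (q - 1L) * pool + i, ] <- dQ[, q, ] / pool
  dY3 <- matrix(dA3a, F2, Tn) * act$g(cache$b3$y)
  bn3g <- bnBackward(dY3, cache$b3, pb$bn3$gamma)
  dP <- bn3g$dx
  dWp <- tcrossprod(dP, cache$Sm)
  dSm <- crossprod(pb$Wp, dP)

  dSa <- array(dSm, c(DF1, Tlen, n))
  dWd <- matrix(0, DF1, K2)
  dZp <- array(0, dim(cache$Zp))
  for (k in seq_len(K2)) {
    sl <- cache$Zp[, k:(k + Tlen - 1L), , drop = FALSE]
    dWd[, k] <- rowSums(dSa * sl, dims = 1L)
    dZp[, k:(k + Tlen - 1L), ] <- dZp[, k:(k + Tlen - 1L), , drop = FALSE] +
      pb$Wd[, k] * dSa
  }
  padL2 <- samePad(K2)[1L]
  dA2d <- matrix(dZp[, padL2 + seq_len(Tlen), , drop = FALSE], DF1, Tn)
  if (!is.null(cache$M2)) dA2d <- dA2d * cache$M2
  dY2 <- dA2d * act$g(cache$b2$y)
  bn2g <- bnBackward(dY2, cache$b2, pb$bn2$gamma)
  dZ <- bn2g$dx

  dWs <- matrix(0, C, DF1)
  dY1 <- matrix(0, F1, C * Tn)
  for (f in seq_len(F1)) {
    rows <- ((f - 1L) * D + 1L):(f * D)
    Hf <- matrix(cache$Y1[f, ], C, Tn)
    dWs[, rows] <- tcrossprod(Hf, dZ[rows, , drop = FALSE])
    dY1[f, ] <- pb$Ws[, rows, drop = FALSE] %*% dZ[rows, , drop = FALSE]
  }
  bn1g <- bnBackward(dY1, cache$b1, pb$bn1$gamma)
  dH1 <- bn1g$dx
  dWt <- tcrossprod(dH1, cache$Xcol)

  dX <- NULL
  if (wantDx) {
    dH1a <- array(dH1, c(F1, C, Tlen, n))
    padL1 <- samePad(K1)[1L]
    dXp <- array(0, c(C, Tlen + K1 - 1L, n))
    for (k in seq_len(K1)) {
      contrib <- colSums(dH1a * pb$Wt[, k], dims = 1L)   # (C, Tlen, n)
      dXp[, k:(k + Tlen - 1L), ] <- dXp[, k:(k + Tlen - 1L), ,
                                        drop = FALSE] + contrib
    }
    dX <- dXp[, padL1 + seq_len(Tlen), , drop = FALSE]
  }
  list(grads = list(Wt = dWt, Ws = dWs, Wd = dWd, Wp = dWp,
                    g1 = bn1g$dgamma, b1 = bn1g$dbeta,
                    g2 = bn2g$dgamma, b2 = bn2g$dbeta,
                    g3 = bn3g$dgamma, b3 = bn3g$dbeta),
       dX = dX)
}

asBranchList <- function(model, X) {
  nb <- length(model@configs)
  if (is.list(X) && !is.array(X)) {
    if (length(X) != nb) stop("one input array required per backbone")
    X
  } else {
    if (nb != 1L) stop("dual-input model requires a list of two arrays")
    list(X)
  }
}

as3d <- function(x) {
  if (is.matrix(x)) array(x, c(dim(x), 1L)) else x
}

# Full forward pass. Returns probabilities, logits and per-branch caches.
cnnForward <- function(model, X, training = FALSE, keepCache = FALSE) {
  Xs <- lapply(asBranchList(model, X), as3d)
  feats <- vector("list", length(Xs))
  caches <- vector("list", length(Xs))
  for (i in seq_along(Xs)) {
    bf <- branchForward(model@params$branches[[i]], model@configs[[i]],
                        Xs[[i]], training, keepCache)
    feats[[i]] <- bf$feat
    caches[[i]] <- bf$cache
    model@params$branches[[i]] <- bf$pb          # refreshed BN stats
  }
  feat <- do.call(rbind, feats)
  z <- drop(model@params$Wfc %*% feat) + model@params$bfc
  list(prob = stats::plogis(z), z = z, feat = feat, caches = caches,
       model = model)
}

#' Classify single trials
#'
#' Evaluation-mode forward pass: dropout off, batch normalization using
#' running statistics, so the output is a deterministic per-trial
#' function of the weights and the input.
#'
#' @param model a \linkS4class{CnnModel}.
#' @param X a C x T matrix, a (C, T, n) array, or for dual-input models a
#'   list with one array per backbone.
#' @return numeric vector of probabilities in [0, 1] (probability of a
#'   right-hand response).
#' @export
predictProb <- function(model, X) {
  unname(cnnForward(model, X, training = FALSE)$prob)
}

#' Threshold a probability into a response label
#'
#' "right" iff the probability strictly exceeds the threshold; an output
#' exactly at the threshold is classified "left".
#'
#' @param probability numeric vector in [0, 1].
#' @param threshold decision threshold.
#' @return factor with levels left/right.
#' @examples
#' predictLabel(c(0.7, 0.5, 0.2))
#' @export
predictLabel <- function(probability, threshold = 0.5) {
  stopifnot(all(probability >= 0 & probability <= 1))
  factor(ifelse(probability > threshold, "right", "left"),
         levels = c("left", "right"))
}

#' Project weights onto their max-norm balls
#'
#' Rescales every depthwise spatial filter (a length-C column) whose L2
#' norm exceeds \code{depthwiseMaxNorm} down to that norm, and the dense
#' weight vector likewise to \code{denseMaxNorm}. Weights already within
#' bounds are untouched; the operation is an idempotent, non-expansive
#' projection applied after every optimizer step.
#'
#' @param model a \linkS4class{CnnModel}.
#' @return the constrained model.
#' @export
constrainWeights <- function(model) {
  for (i in seq_along(model@params$branches)) {
    cfg <- model@configs[[i]]
    Ws <- model@params$branches[[i]]$Ws
    norms <- sqrt(colSums(Ws ^ 2))
    scale <- ifelse(norms > cfg@depthwiseMaxNorm & norms > 0,
                    cfg@depthwiseMaxNorm / norms, 1)
    model@params$branches[[i]]$Ws <- Ws * rep(scale, each = nrow(Ws))
  }
  maxn <- model@configs[[1L]]@denseMaxNorm
  wn <- sqrt(sum(model@params$Wfc ^ 2))
  if (wn > maxn) model@params$Wfc <- model@params$Wfc * (maxn / wn)
  model
}

#' Per-layer trainable parameter counts
#'
#' Closed-form counts for each layer of the architecture: temporal
#' convolution K*F1, its batch-norm 2*F1, depthwise spatial convolution
#' C*D*F1, batch-norm 2*D*F1, separable convolution
#' K*D*F1 + F2*(D*F1), batch-norm 2*F2, and the dense head
#' F2*(T %/% pool) + 1 (its bias included).
#'
#' @param cfg a \linkS4class{ModelConfig}.
#' @return list with \code{layers} (data.frame layer/params) and
#'   \code{total}.
#' @export
countParameters <- function(cfg) {
  DF1 <- cfg@D * cfg@F1
  layers <- data.frame(
    layer = c("Conv2D", "BatchNorm", "DepthwiseConv2D", "BatchNorm",
              "SeparableConv2D", "BatchNorm", "Dense"),
    params = c(cfg@temporalKernel * cfg@F1, 2L * cfg@F1,
               cfg@C * DF1, 2L * DF1,
               cfg@separableKernel * DF1 + cfg@F2 * DF1, 2L * cfg@F2,
               featureLength(cfg) + 1L))
  list(layers = layers, total = sum(layers$params))
}

#' Total trainable elements of a built model
#'
#' Brute-force enumeration over the stored weight arrays (convolution and
#' dense weights, batch-norm scale and shift; running statistics are not
#' trainable).
#'
#' @param model a \linkS4class{CnnModel}.
#' @return integer count.
#' @export
nTrainable <- function(model) {
  nb <- sum(vapply(model@params$branches, function(pb) {
    length(pb$Wt) + length(pb$Ws) + length(pb$Wd) + length(pb$Wp) +
      length(pb$bn1$gamma) + length(pb$bn1$beta) +
      length(pb$bn2$gamma) + length(pb$bn2$beta) +
      length(pb$bn3$gamma) + length(pb$bn3$beta)
  }, numeric(1)))
  as.integer(nb + length(model@params$Wfc) + 1L)
}

#' Layer-by-layer network description
#'
#' A table mirroring the architecture summary: layer, filter count,
#' kernel size, trainable parameters, and output shape.
#'
#' @param cfg a \linkS4class{ModelConfig}.
#' @return data.frame.
#' @examples
#' networkSpec(modelConfig())
#' @export
networkSpec <- function(cfg) {
  DF1 <- cfg@D * cfg@F1
  Tp <- cfg@T %/% cfg@pool
  cnt <- countParameters(cfg)$layers$params
  sh <- function(...) paste0("(", paste(..., sep = ", "), ")")
  data.frame(
    layer = c("Input", "Reshape", "Conv2D", "BatchNorm", "DepthwiseConv2D",
              "BatchNorm", "Activation", "Dropout", "SeparableConv2D",
              "BatchNorm", "Activation", "AveragePool2D", "Dropout",
              "Flatten", "Dense"),
    size = c("", "", sh(1, cfg@temporalKernel), "", sh(cfg@C, 1), "", "",
             "", sh(1, cfg@separableKernel), "", "", sh(1, cfg@pool), "",
             "", ""),
    params = c(0L, 0L, cnt[1L], cnt[2L], cnt[3L], cnt[4L], 0L, 0L, cnt[5L],
               cnt[6L], 0L, 0L, 0L, 0L, cnt[7L]),
    output = c(sh(cfg@C, cfg@T), sh(1, cfg@C, cfg@T),
               sh(cfg@F1, cfg@C, cfg@T), sh(cfg@F1, cfg@C, cfg@T),
               sh(DF1, 1, cfg@T), sh(DF1, 1, cfg@T), sh(DF1, 1, cfg@T),
               sh(DF1, 1, cfg@T), sh(cfg@F2, 1, cfg@T),
               sh(cfg@F2, 1, cfg@T), sh(cfg@F2, 1, cfg@T),
               sh(cfg@F2, 1, Tp), sh(cfg@F2, 1, Tp),
               as.character(cfg@F2 * Tp), "1"))
}

# Observed intermediate shapes from a forward pass on random input;
# used to verify the shape chain against networkSpec().
observedShapes <- function(model, n = 2L) {
  cfg <- model@configs[[1L]]
  X <- array(stats::rnorm(cfg@C * cfg@T * n), c(cfg@C, cfg@T, n))
  fw <- cnnForward(model, if (length(model@configs) > 1L)
    replicate(length(model@configs), X, simplify = FALSE) else X,
    keepCache = TRUE)
  fw$caches[[1L]]$shapes
}
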