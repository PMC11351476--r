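# Architecture construction, parameter accounting, forward semantics,
# max-norm projection, dual-input variant.

test_that("layer parameter formulas instantiate correctly", {
  cfg <- modelConfig(C = 42L, T = 56L, F1 = 8L, D = 2L, F2 = 16L)
  cp <- countParameters(cfg)
  pl <- setNames(cp$layers$params, make.unique(cp$layers$layer))
  expect_equal(unname(pl["DepthwiseConv2D"]), 42 * 2 * 8)   # 672
  expect_equal(unname(pl["BatchNorm"]), 2 * 8)              # 16
  expect_equal(unname(pl["Dense"]), 16 * (56 %/% 8) + 1)    # 113
  cp4 <- countParameters(modelConfig(F1 = 4L))
  expect_equal(cp4$layers$params[1], 20 * 4)                # 80
  # dense input length F2 * (T %/% 8)
  expect_equal(erosbci:::featureLength(cfg), 112L)
})

test_that("counts and shapes match brute force for random architectures", {
  set.seed(10)
  for (i in 1:20) {
    cfg <- randomArchConfig()
    model <- buildNetwork(cfg, seed = i)
    expect_identical(nTrainable(model), as.integer(countParameters(cfg)$total))
    sh <- erosbci:::observedShapes(model)
    DF1 <- cfg@D * cfg@F1
    expect_equal(sh$conv, c(cfg@F1, cfg@C, cfg@T))
    expect_equal(sh$depthwise, c(DF1, 1L, cfg@T))
    expect_equal(sh$separable, c(cfg@F2, 1L, cfg@T))
    expect_equal(sh$pool, c(cfg@F2, 1L, cfg@T %/% cfg@pool))
    expect_equal(sh$flatten, cfg@F2 * (cfg@T %/% cfg@pool))
  }
})

test_that("the depthwise stage collapses the spatial extent for any C", {
  for (C in c(6L, 42L, 30L)) {
    m <- buildNetwork(modelConfig(C = C, T = 24L, F1 = 2L, D = 2L, F2 = 4L),
                      seed = 1)
    expect_equal(erosbci:::observedShapes(m)$depthwise[2], 1L)
  }
})

test_that("forward outputs probabilities and is deterministic in eval mode", {
  cfg <- tinyModelConfig(dropout = 0.5)
  m <- buildNetwork(cfg, seed = 2)
  set.seed(3)
  X <- array(rnorm(6 * 16 * 4), c(6, 16, 4))
  p <- predictProb(m, X)
  expect_true(all(p >= 0 & p <= 1))
  # duplicated input in one batch gives identical outputs
  Xdup <- array(c(X[, , 1], X[, , 1]), c(6, 16, 2))
  pd <- predictProb(m, Xdup)
  expect_identical(pd[1], pd[2])
  # and repeated calls agree to machine precision
  expect_identical(predictProb(m, X), p)
  expect_error(predictProb(m, array(rnorm(5 * 16), c(5, 16, 1))),
               "shape")
})

test_that("a zeroed dense head outputs exactly 0.5", {
  m <- buildNetwork(tinyModelConfig(), seed = 4)
  m@params$Wfc[] <- 0
  m@params$bfc <- 0
  set.seed(5)
  expect_equal(predictProb(m, matrix(rnorm(6 * 16), 6, 16)), 0.5)
})

test_that("max-norm constraint is an idempotent non-expansive projection", {
  cfg <- tinyModelConfig()
  m <- buildNetwork(cfg, seed = 6)
  # inflate a spatial filter and the dense row beyond their bounds
  m@params$branches[[1]]$Ws[, 1] <- m@params$branches[[1]]$Ws[, 1] * 50
  m@params$Wfc <- m@params$Wfc * 50
  c1 <- constrainWeights(m)
  expect_equal(sqrt(sum(c1@params$branches[[1]]$Ws[, 1] ^ 2)), 1)
  expect_equal(sqrt(sum(c1@params$Wfc ^ 2)), 0.25)
  # weights already within bounds are untouched
  small <- m
  small@params$branches[[1]]$Ws[] <- 0.1
  small@params$Wfc[] <- 1e-3
  c2 <- constrainWeights(small)
  expect_identical(c2@params$branches[[1]]$Ws, small@params$branches[[1]]$Ws)
  expect_identical(c2@params$Wfc, small@params$Wfc)
  # idempotence and non-expansiveness on random inflations
  set.seed(7)
  m@params$branches[[1]]$Ws <- matrix(rnorm(6 * 2, sd = 2), 6, 2)
  once <- constrainWeights(m)
  twice <- constrainWeights(once)
  expect_identical(once@params, twice@params)
  expect_true(all(sqrt(colSums(once@params$branches[[1]]$Ws ^ 2)) <=
                    sqrt(colSums(m@params$branches[[1]]$Ws ^ 2)) + 1e-12))
})

test_that("label thresholding matches the two-branch rule on a fine grid", {
  p <- seq(0, 1, length.out = 1001)
  got <- predictLabel(p, 0.5)
  oracle <- factor(vapply(p, function(x) if (x > 0.5) "right" else "left",
                          character(1)), levels = c("left", "right"))
  expect_identical(got, oracle)
  expect_identical(as.character(predictLabel(0.7)), "right")
  expect_identical(as.character(predictLabel(0.5)), "left")  # strict exceed
})

test_that("the dual-input network concatenates backbone features", {
  ca <- tinyModelConfig(F2 = 4L)
  cb <- tinyModelConfig(F2 = 8L)
  dm <- buildDual(ca, cb, seed = 8)
  expect_equal(ncol(dm@params$Wfc),
               4L * (16L %/% 4L) + 8L * (16L %/% 4L))
  dm@params$Wfc[] <- 0
  set.seed(9)
  X <- list(matrix(rnorm(6 * 16), 6, 16), matrix(rnorm(6 * 16), 6, 16))
  expect_equal(predictProb(dm, X), 0.5)
  expect_error(buildDual(ca, modelConfig(C = 6L, T = 20L, F1 = 2L, D = 1L,
                                         F2 = 4L, temporalKernel = 5L,
                                         separableKernel = 5L, pool = 4L)),
               "mismatched T")
})

test_that("a zeroed branch with identity batch-norm cannot influence a dual model", {
  ca <- tinyModelConfig()
  freezeBn <- function(m, branch) {
    for (nm in c("bn1", "bn2", "bn3")) {
      bn <- m@params$branches[[branch]][[nm]]
      bn$gamma[] <- 1; bn$beta[] <- 0; bn$rm[] <- 0; bn$rv[] <- 1 - 1e-5
      m@params$branches[[branch]][[nm]] <- bn
    }
    m
  }
  d1 <- freezeBn(buildDual(ca, ca, seed = 10), 2L)
  d2 <- d1
  # replace the intensity-branch weights entirely
  set.seed(11)
  d2@params$branches[[2]]$Wt[] <- rnorm(length(d2@params$branches[[2]]$Wt))
  d2 <- constrainWeights(freezeBn(d2, 2L))
  phase <- matrix(rnorm(6 * 16), 6, 16)
  zero <- matrix(0, 6, 16)
  expect_equal(predictProb(d1, list(phase, zero)),
               predictProb(d2, list(phase, zero)))
})

test_that("the network spec table chains output shapes consistently", {
  ns <- networkSpec(modelConfig())
  expect_equal(nrow(ns), 15L)
  expect_equal(ns$output[ns$layer == "Flatten"], "112")
  expect_equal(sum(ns$params), countParameters(modelConfig())$total)
})
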