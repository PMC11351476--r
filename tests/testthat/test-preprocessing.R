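# Fast-optical-signal pre-processing chain.

test_that("phase unwrapping is identity on smooth series and inverts wraps", {
  expect_equal(unwrapPhase(rep(5, 20), 360), rep(5, 20))
  # ramp wrapping once at +period/2
  ramp <- seq(0, 300, by = 20)
  wrapped <- ifelse(ramp > 180, ramp - 360, ramp)
  expect_equal(unwrapPhase(wrapped, 360), ramp)
  expect_true(all(diff(unwrapPhase(wrapped, 360)) == 20))
  # synthetic wrapping oracle: recover an arbitrary smooth series
  set.seed(1)
  x <- cumsum(rnorm(300, sd = 20))
  xw <- ((x + 180) %% 360) - 180
  rec <- unwrapPhase(xw, 360)
  expect_equal(rec - rec[1], x - x[1], tolerance = 1e-10)
  expect_error(unwrapPhase(c(1, NA, 3), 360), "finite")
})

test_that("pulse regression removes the reference and its quadrature", {
  t <- seq(0, 10, by = 1 / 39.0625)
  ref <- sin(2 * pi * 1.2 * t)
  # exact collinearity
  expect_lt(max(abs(regressPulse(3 * ref, ref))), 1e-10)
  # a series already orthogonal to the regressors is unchanged
  set.seed(1)
  orth <- regressPulse(rnorm(length(t)), ref)
  expect_equal(regressPulse(orth, ref), orth, tolerance = 1e-8)
  # signal + 0.7 * shifted pulse recovered
  set.seed(2)
  sig <- as.numeric(stats::filter(rnorm(length(t)), rep(1 / 5, 5),
                                  sides = 2))
  sig[is.na(sig)] <- 0
  series <- sig + 0.7 * sin(2 * pi * 1.2 * t + 1.1)
  res <- regressPulse(series, ref)
  expect_lt(abs(cor(res, ref)), 1e-10)
  expect_gt(cor(res, sig), 0.95)
  expect_error(regressPulse(sig, rep(1, length(t))), "zero variance")
})

test_that("channel QC applies the three inclusion predicates", {
  cfg <- preprocessConfig()
  ch <- function(d, p, a) list(distance = d, phaseSd = p, meanAc = a)
  expect_length(qcChannels(list(ch(1.5, 100, 200)), cfg), 0)  # too close
  expect_length(qcChannels(list(ch(3, 150, 120)), cfg), 1)
  # boundary handling: distance inclusive, phaseSd/meanAc strict
  expect_length(qcChannels(list(ch(2, 100, 200)), cfg), 1)
  expect_length(qcChannels(list(ch(7, 100, 200)), cfg), 1)
  expect_length(qcChannels(list(ch(3, 200, 200)), cfg), 0)
  expect_length(qcChannels(list(ch(3, 100, 100)), cfg), 0)
})

test_that("channel QC equals the brute-force predicate filter and is idempotent", {
  cfg <- preprocessConfig()
  set.seed(3)
  recs <- lapply(1:100, function(i)
    list(distance = runif(1, 0, 9), phaseSd = runif(1, 0, 400),
         meanAc = runif(1, 0, 300), id = i))
  kept <- qcChannels(recs, cfg)
  oracle <- Filter(function(r)
    r$distance >= 2 && r$distance <= 7 && r$phaseSd < 200 && r$meanAc > 100,
    recs)
  expect_identical(kept, oracle)
  expect_identical(qcChannels(kept, cfg), kept)        # idempotent
})

test_that("voxel projection is the per-voxel unweighted channel mean", {
  one <- list(list(series = sin(1:50), voxelTargets = 3L))
  pr <- projectVoxels(one, 5L)
  expect_equal(pr[3, ], sin(1:50))
  expect_equal(attr(pr, "viable"), c(FALSE, FALSE, TRUE, FALSE, FALSE))
  # cancellation
  s <- rnorm(20)
  two <- list(list(series = s, voxelTargets = 2L),
              list(series = -s, voxelTargets = 2L))
  expect_equal(max(abs(projectVoxels(two, 3L)[2, ])), 0)
  # random mapping equals brute-force group means
  set.seed(4)
  chans <- lapply(1:12, function(i)
    list(series = rnorm(30), voxelTargets = sample(1:5, 1)))
  pr <- projectVoxels(chans, 5L)
  for (v in 1:5) {
    members <- Filter(function(ch) ch$voxelTargets == v, chans)
    if (length(members)) {
      expected <- colMeans(do.call(rbind, lapply(members, `[[`, "series")))
      expect_equal(pr[v, ], expected)
    } else expect_equal(max(abs(pr[v, ])), 0)
  }
})

test_that("max-abs scaling normalizes globally and preserves structure", {
  set.seed(5)
  ep <- matrix(rnorm(42 * 56), 42, 56)
  ep[7, 13] <- 4                       # known global max
  sc <- scaleMaxAbs(ep)
  expect_equal(max(abs(sc)), 1)
  expect_equal(which.max(abs(sc)), which.max(abs(ep)))
  expect_equal(sc * 4, ep)             # all ratios preserved
  zero <- matrix(0, 3, 4)
  expect_identical(scaleMaxAbs(zero), zero)
})

test_that("epochs have the contracted 56-sample length at defaults", {
  expect_equal(epochLength(39.0625, 716), 56L)
  expect_equal(timeToSample(179), 35L)
  expect_equal(timeToSample(410), 44L)
})

test_that("preprocessing a constant block yields all-zero epochs", {
  cfg <- preprocessConfig()
  block <- matrix(7.3, 5, 600)
  pp <- preprocessBlock(block, events = c(200, 400), cfg)
  expect_length(pp$epochs, 2)
  for (ep in pp$epochs) {
    expect_equal(dim(ep), c(5L, 56L))
    expect_equal(max(abs(ep)), 0)
  }
})

test_that("events too close to the block edge are skipped with a warning", {
  cfg <- preprocessConfig()
  set.seed(6)
  block <- matrix(rnorm(5 * 400), 5, 400)
  expect_warning(pp <- preprocessBlock(block, events = c(10, 200), cfg,
                                       labels = c("left", "right")),
                 "skipped")
  expect_length(pp$epochs, 1)
  expect_equal(as.character(pp$labels), "right")
})

test_that("the band-pass strongly attenuates sub-band drift", {
  cfg <- preprocessConfig(band = c(0.1, 12))
  fs <- cfg@fs
  t <- seq(0, 120, by = 1 / fs)
  slow <- matrix(sin(2 * pi * 0.05 * t), 1)
  filtered <- erosbci:::bandPass(slow, cfg@band, fs)
  core <- seq(round(length(t) * 0.25), round(length(t) * 0.75))
  expect_lt(sqrt(mean(filtered[core] ^ 2)), 0.1 * sqrt(mean(slow[core] ^ 2)))
})

test_that("the zero-phase filter preserves symmetry of a symmetric pulse", {
  cfg <- preprocessConfig()
  n <- 1001
  x <- matrix(0, 1, n)
  x[1, ] <- exp(-((seq_len(n) - 501) / 20) ^ 2)
  y <- erosbci:::bandPass(x, cfg@band, cfg@fs)[1, ]
  asym <- max(abs(y - rev(y)))
  expect_lt(asym, 1e-6 * max(abs(y)))
})

test_that("baseline correction zeroes the pre-response window mean", {
  cfg <- preprocessConfig()
  set.seed(7)
  block <- matrix(rnorm(4 * 800), 4, 800)
  seg <- segmentEpochs(block, events = c(300, 500), cfg)
  expect_equal(seg$nBaseline, 39L)
  for (ep in seg$epochs) {
    bm <- rowMeans(ep[, seq_len(seg$nBaseline), drop = FALSE])
    expect_lt(max(abs(bm)), 1e-9)
  }
  # and cropping retains 28 samples either side of the response
  cr <- cropEpoch(seg$epochs[[1]], seg$nBaseline, cfg)
  expect_equal(ncol(cr), 56L)
})

test_that("the qc report mirrors the filter decisions", {
  cfg <- preprocessConfig()
  recs <- list(list(distance = 3, phaseSd = 100, meanAc = 150),
               list(distance = 8, phaseSd = 100, meanAc = 150))
  rep <- qcReport(recs, cfg)
  expect_equal(rep$kept, c(TRUE, FALSE))
})
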