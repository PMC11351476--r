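# Synthetic EROS generator: montage structure, planted effect, noise
# statistics, determinism.

test_that("degenerate quality ranges give a fully viable montage", {
  cfg <- simConfig(voxelDropoutRange = c(0, 0),
                   channelsPerVoxelRange = c(4L, 4L), seed = 1)
  ms <- makeMontageSpec(cfg, "A")
  expect_true(all(viableVoxels(ms)))
  expect_true(all(channelsPerVoxel(ms) == 4L))
})

test_that("montage specs are deterministic in (seed, montage id)", {
  cfg <- simConfig(seed = 9)
  a1 <- makeMontageSpec(cfg, "B")
  a2 <- makeMontageSpec(cfg, "B")
  expect_identical(a1@viableVoxelMask, a2@viableVoxelMask)
  expect_identical(a1@channelsPerVoxel, a2@channelsPerVoxel)
  b <- makeMontageSpec(cfg, "C")
  expect_false(identical(a1@viableVoxelMask, b@viableVoxelMask))
})

test_that("a dropout range producing no viable voxels errors", {
  cfg <- simConfig(seed = 1)
  cfg@voxelDropoutRange <- c(0.999, 0.999)
  expect_error(makeMontageSpec(cfg, "A"), "no viable voxels")
})

test_that("mean viable fraction tracks the configured dropout range", {
  fracs <- vapply(1:1000, function(s) {
    ms <- makeMontageSpec(simConfig(voxelDropoutRange = c(0.1, 0.3),
                                    seed = s), "A")
    mean(viableVoxels(ms))
  }, numeric(1))
  expect_gte(mean(fracs), 0.70)
  expect_lte(mean(fracs), 0.90)
})

test_that("zero-noise trials equal the deterministic template exactly", {
  cfg <- simConfig(noiseSd = 0, pulseAmplitude = 0,
                   voxelDropoutRange = c(0, 0),
                   channelsPerVoxelRange = c(2L, 2L), seed = 2)
  ms <- makeMontageSpec(cfg, "A")
  set.seed(1)
  tr <- generateTrial("right", ms, cfg)
  expect_equal(tr, effectTemplate("right", cfg, ms))
})

test_that("left and right templates are equal magnitude, opposite sign", {
  cfg <- simConfig(seed = 3)
  tl <- effectTemplate("left", cfg)
  tr <- effectTemplate("right", cfg)
  expect_equal(tl, -tr)
  v <- cfg@effectVoxel
  expect_gt(max(abs(tr[v, ])), 0)
  # right hemisphere carries 1.5x the mirrored left-hemisphere amplitude
  expect_equal(tr[v, ], 1.5 * tr[mirrorVoxel(v, cfg@nVoxels), ])
})

test_that("unknown labels and modalities are rejected", {
  cfg <- simConfig(seed = 1)
  ms <- makeMontageSpec(cfg, "A")
  expect_error(generateTrial("up", ms, cfg), "unknown label")
  expect_error(generateTrial("left", ms, cfg, modality = "ac"),
               "unknown modality")
})

test_that("zero effect amplitude yields indistinguishable classes", {
  cfg <- simConfig(effectAmplitude = 0, voxelDropoutRange = c(0, 0),
                   channelsPerVoxelRange = c(2L, 2L), seed = 4)
  ms <- makeMontageSpec(cfg, "A")
  v <- cfg@effectVoxel
  idx <- timeToSample(179, cfg@fs)
  set.seed(11)
  xl <- vapply(1:250, function(i) generateTrial("left", ms, cfg)[v, idx],
               numeric(1))
  xr <- vapply(1:250, function(i) generateTrial("right", ms, cfg)[v, idx],
               numeric(1))
  expect_lt(abs(t.test(xl, xr)$statistic), 4)
})

test_that("the class separation grows with effect amplitude", {
  v <- simConfig(seed = 1)@effectVoxel
  idx <- timeToSample(179)
  tstats <- vapply(c(0, 0.5, 1, 2), function(a) {
    cfg <- simConfig(effectAmplitude = a, noiseSd = 1,
                     voxelDropoutRange = c(0, 0),
                     channelsPerVoxelRange = c(2L, 2L), seed = 5)
    ms <- makeMontageSpec(cfg, "A")
    set.seed(17)
    xl <- vapply(1:250, function(i) generateTrial("left", ms, cfg)[v, idx],
                 numeric(1))
    xr <- vapply(1:250, function(i) generateTrial("right", ms, cfg)[v, idx],
                 numeric(1))
    unname(t.test(xr, xl)$statistic)
  }, numeric(1))
  expect_true(all(diff(tstats) > 0))
})

test_that("per-voxel noise SD scales as 1/sqrt(channels per voxel)", {
  cfg <- simConfig(effectAmplitude = 0, pulseAmplitude = 0, seed = 6)
  C <- cfg@nVoxels
  ms <- new("MontageSpec", montageId = "A",
            viableVoxelMask = rep(TRUE, C),
            channelsPerVoxel = rep(c(1L, 4L), length.out = C),
            latencyOffsetMs = 0)
  set.seed(21)
  sds <- matrix(0, C, 1000)
  for (i in 1:1000) sds[, i] <- apply(generateTrial("left", ms, cfg), 1, sd)
  meanSd <- rowMeans(sds)
  ratio <- mean(meanSd[channelsPerVoxel(ms) == 1L]) /
    mean(meanSd[channelsPerVoxel(ms) == 4L])
  expect_gt(ratio, 1.8)
  expect_lt(ratio, 2.2)
})

test_that("subject datasets have the designed trial arithmetic", {
  cfg <- simConfig(nMontages = 1L, nBlocks = 4L, seed = 7)
  ds <- generateSubjectDataset(cfg, "S1", modalities = "phase")
  s <- ds$A$phase
  # 4 blocks x 24 trials x 0.5 manual = 48 trials, balanced
  expect_equal(nTrials(s), 48L)
  expect_equal(sum(trialLabels(s) == "left"), 24L)
  expect_equal(sum(trialLabels(s) == "right"), 24L)
  # label balance holds within every block
  for (b in unique(trialBlocks(s))) {
    lb <- trialLabels(s)[trialBlocks(s) == b]
    expect_equal(sum(lb == "left"), sum(lb == "right"))
  }
  expect_equal(dim(trialData(s))[1:2], c(42L, 56L))
})

test_that("manualFraction = 1 with one block of 10 gives 10 trials", {
  cfg <- simConfig(nMontages = 1L, nBlocks = 1L, trialsPerBlock = 10L,
                   manualFraction = 1, seed = 8)
  ds <- generateSubjectDataset(cfg, "S1", modalities = "phase")
  expect_equal(nTrials(ds$A$phase), 10L)
})

test_that("dataset generation is bitwise deterministic", {
  cfg <- simConfig(nMontages = 2L, nBlocks = 2L, seed = 12)
  d1 <- generateSubjectDataset(cfg, "S2", modalities = "phase")
  d2 <- generateSubjectDataset(cfg, "S2", modalities = "phase")
  expect_identical(trialData(d1$B$phase), trialData(d2$B$phase))
  expect_identical(trialLabels(d1$A$phase), trialLabels(d2$A$phase))
})
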