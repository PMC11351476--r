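# Small fixtures shared across test files; everything is generated in
# code, no stored data.

tinyModelConfig <- function(...) {
  args <- modifyList(list(C = 6L, T = 16L, F1 = 2L, D = 1L, F2 = 4L,
                          temporalKernel = 5L, separableKernel = 5L,
                          pool = 4L, dropout = 0), list(...))
  do.call(modelConfig, args)
}

# Epoch-level toy dataset for model/training tests: a lateralized bump at
# voxel `effectVoxel`, samples 8..12, sign flipped by label, plus white
# noise. Returns a TrialSet with C = 6, T = 16.
toyTrialSet <- function(n, amp = 1, noise = 0.2, seed = 1, C = 6L,
                        Tlen = 16L, effectVoxel = 5L) {
  stopifnot(n %% 2 == 0)
  labels <- rep(c("left", "right"), length.out = n)
  bump <- exp(-(seq_len(Tlen) - 10) ^ 2 / 4)
  X <- array(0, c(C, Tlen, n))
  set.seed(seed)
  for (i in seq_len(n)) {
    sgn <- if (labels[i] == "right") 1 else -1
    tr <- matrix(rnorm(C * Tlen, sd = noise), C, Tlen)
    tr[effectVoxel, ] <- tr[effectVoxel, ] + sgn * amp * bump
    X[, , i] <- tr
  }
  trialSet(X, labels, fs = 39.0625)
}

quickTrainConfig <- function(...) {
  args <- modifyList(list(maxEpochs = 12L, patience = 4L,
                          learningRate = 5e-3, batchSize = 16L),
                     list(...))
  do.call(trainConfig, args)
}

# A full-pipeline planted-effect dataset (one montage, phase modality).
plantedDataset <- function(seed, effectAmplitude = 3, nBlocks = 20L) {
  cfg <- simConfig(nMontages = 1L, nBlocks = nBlocks,
                   effectAmplitude = effectAmplitude, noiseSd = 1,
                   seed = seed)
  generateSubjectDataset(cfg, "S1", modalities = "phase")$A$phase
}

randomArchConfig <- function() {
  C <- 2L * sample(2:24, 1)
  Tlen <- sample(16:64, 1)
  modelConfig(C = C, T = Tlen, F1 = sample(c(2L, 4L, 8L, 16L), 1),
              D = sample(1:4, 1), F2 = sample(c(4L, 8L, 16L, 32L), 1),
              temporalKernel = sample(3:min(20L, Tlen), 1),
              separableKernel = sample(3:min(20L, Tlen), 1),
              pool = sample(2:min(8L, Tlen), 1))
}
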