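---
title: "Single-trial decoding of event-related optical signals: models, assumptions and design choices"
author: "erosbci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-trial decoding of event-related optical signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erosbci)
```

## The problem

Event-related optical signals (EROS) are fast changes — on the order of
100 ms — in near-infrared light scattering that accompany neuronal
activity. Frequency-domain optical instruments record them as two
co-registered modalities: *phase delay* (photon time-of-flight, in
picoseconds, spatially sharp) and *DC intensity* (average detected light,
spatially blurrier but measurable with much simpler hardware). Because
single-trial EROS has a very low signal-to-noise ratio, almost all prior
work averaged many trials before analysis, which caps the information
rate any brain–computer interface built on it could reach.

`erosbci` implements a complete single-trial decoding pipeline for
motor-response EROS: given one epoch of voxel-projected optical data
surrounding a left- or right-hand key press, predict which hand
responded. The pipeline covers synthetic data generation, signal
pre-processing, a compact convolutional classifier, subject-specific
training paradigms, evaluation statistics, and feature attribution.

## The synthetic data generator

Real single-trial optical recordings of this kind are not publicly
archived, so the package ships a generator (`simConfig()`,
`generateSubjectDataset()`) that emulates the statistical structure the
analysis relies on. Its defaults are the study conditions of the
experimental design it mirrors:

* **Design.** 20 blocks of 24 trials per montage, half of them manual
  responses, giving 240 labelled trials per montage; sampling rate
  39.0625 Hz; up to four montages labelled A–D per subject.
* **Geometry.** A flattened 42-voxel grid, split 21/21 between a left-
  and a right-hemisphere 3 × 7 grid covering a 6 × 7 cm region of
  interest over motor cortex. How the 42 input voxels map onto the two
  hemispheres is not uniquely determined by the source material; the
  even split is this package's choice and `nVoxels` is configurable.
* **Planted effect.** A hand-lateralized deflection made of two Gaussian
  bumps (σ = 50 ms) centred 179 ms and 410 ms after the response, placed
  in a right-hemisphere "hand" voxel (amplitude 1.5×) and its
  left-hemisphere mirror (1×), with polarity flipped between right- and
  left-hand responses (positive for right). The latencies are empirical;
  the Gaussian waveform is the simplest unimodal deflection consistent
  with them, and the 1.5× hemispheric asymmetry encodes the finding that
  right-hemisphere data are more discriminative in right-handed
  subjects, whose left hemisphere activates for both hands.
* **Noise.** Per-voxel white noise (SD `noiseSd`, the amplitude unit of
  the effect), 1/f "pink" noise produced by spectral shaping of white
  noise (`pinkExponent`, default 1), and a shared sinusoidal pulse
  artifact (default 1.2 Hz, random phase per block) standing in for the
  cardiac signal; a physiologically detailed pulse model is deliberately
  out of scope. Channel-level physics is collapsed to voxel level: a
  voxel served by *k* channels has its noise SD scaled by 1/√k,
  reflecting channel averaging; full photon-transport simulation is a
  non-goal.
* **Montage quality.** Each montage draws a fraction of non-viable
  voxels from `voxelDropoutRange` (default 10–30%) and a channel count
  per viable voxel from `channelsPerVoxelRange` (default 1–6),
  emulating the observed variation of 60–84 viable voxels out of 98 and
  1.6–5.4 channels per voxel across real montages. `spatialOffsetMs`
  (default 0) can jitter the effect latency per montage to emulate
  inter-montage misalignment.
* **Intensity modality.** Generated with the effect attenuated
  (`intensityEffectScale`, default 0.5) and pink noise amplified
  (`intensityPinkScale`, default 3), reflecting intensity's
  susceptibility to low-frequency contamination.

Every quantity is a deterministic function of `(seed, subject, montage,
block)`, so datasets are bitwise reproducible.

What the generator does **not** emulate: instrument physics
(modulation at 110/300 MHz, phase-to-picosecond calibration), head
geometry and diffusion-path reconstruction, realistic cardiac and
respiratory waveforms, artifacts from movement, and the spatial
correlation structure of real optical noise. Passing tests on this
synthetic data therefore demonstrate that the pipeline's machinery is
correct and can recover a known planted effect — not that real EROS data
contain one of this size.

## Pre-processing

`preprocessBlock()` applies, in order: per-block mean centring per
voxel; a zero-phase 4th-order Butterworth band-pass (default
0.1–12 Hz; narrow bands 4–7, 8–13, 13–20 Hz are supported
configurations); segmentation time-locked to each response; per-voxel
baseline correction over the 998 ms window preceding the response; and
cropping to ±716 ms around the response. At 39.0625 Hz that yields
round(0.716 × 39.0625) = 28 samples per side — a 56-sample epoch with
the response at sample 28 — and a 39-sample baseline window. Finally
each epoch is scaled by its single global maximum absolute value
(`scaleMaxAbs()`), so the network input lies in [−1, 1].

Numerical choices worth knowing:

* **Filtering.** The forward–backward (zero-phase) Butterworth response
  is applied in the frequency domain as the filter's squared magnitude,
  with odd-reflection padding over several low-cutoff time constants.
  This is numerically equivalent to forward–backward time-domain
  filtering but exactly zero-phase and free of its edge transients,
  which matters because the 0.1 Hz high-pass has an impulse response
  lasting tens of seconds.
* **Ordering.** Centring precedes filtering, and baseline correction
  follows segmentation, matching the stated order of the chain; the
  band-pass has no DC gain, so a constant block maps to all-zero
  epochs.
* **Scaling scope.** Max-abs scaling is per trial, not per dataset, so
  test-time scaling needs no training statistics.
* **Channel quality control.** `qcChannels()` keeps a channel iff its
  source–detector distance lies in the inclusive interval [2, 7] cm,
  its phase SD is strictly below 200, and its mean raw AC is strictly
  above 100 mV — boundary strictness follows the wording "less than" /
  "over". The units of the phase-SD threshold are not stated in the
  source material; the threshold is a plain configurable number.
* **Voxel projection.** `projectVoxels()` uses the unweighted mean of
  all channels mapping to a voxel. This is a declared simplification of
  diffusion-path-weighted reconstruction, which requires head geometry
  the package does not model.
* **Phase unwrapping** (`unwrapPhase()`) removes successive-sample
  jumps larger than half the wrap period; **pulse regression**
  (`regressPulse()`) projects out a pulse reference and its quadrature,
  accommodating arbitrary pulse phase.

## The classifier

`buildNetwork()` constructs a compact depthwise-separable CNN in the
EEGNet family, written directly in vectorised R:

| stage | operation | parameters |
|---|---|---|
| temporal | F1 filters of (1, 20), same padding, no bias | 20·F1 |
| | batch-norm | 2·F1 |
| spatial | depthwise (C, 1), D filters per temporal filter, max-norm 1 | C·D·F1 |
| | batch-norm, ELU, dropout 0.5 | 2·D·F1 |
| separable | depthwise (1, 20) + pointwise (1, 1) to F2, no bias | 20·D·F1 + F2·D·F1 |
| | batch-norm, ELU, average-pool (1, 8), dropout | 2·F2 |
| head | dense F2·(T ÷ 8) → 1 + sigmoid, max-norm 0.25 | F2·(T ÷ 8) + 1 |

A probability above the fixed threshold 0.5 is classified as a right
motor response; exactly 0.5 is left ("exceeds" is strict). The (1, 20)
temporal kernel spans half the ~40 Hz sampling rate, i.e. about 500 ms
of signal. `countParameters()` gives the closed-form accounting and
`networkSpec()` the layer table; both are verified against brute-force
enumeration in the tests.

Design details that the architecture description leaves open, fixed
here for reproducibility:

* Same padding with the even kernel 20 is asymmetric: 9 samples left,
  10 right.
* Max-norm constraints are enforced by projection after **every**
  optimizer step (`constrainWeights()`, an idempotent non-expansive
  projection).
* Batch normalization uses momentum 0.1 and ε = 10⁻⁵; running
  statistics are used in evaluation mode, making evaluation a pure
  per-trial function.
* The dense layer keeps its bias; convolutions have none.
* Default (F1, D, F2) = (8, 2, 16) is the centre of the search space.
* Initialization is Glorot-uniform.

`buildDual()` builds the dual-modality variant: one backbone per input
type, flattened features concatenated into a single dense sigmoid head.

## Training

`fitNetwork()` minimizes binary cross-entropy for up to 300 epochs
(default batch size 32, a choice the source material does not state)
with early stopping on a configurable validation metric (accuracy,
AUROC, or loss; patience 50 epochs) and restores the best epoch's
weights. `makeSplits()` holds out 20% of trials stratified by label
(and montage in pooled runs) and partitions the rest into 5
cross-validation folds — read here as fold partitions of the 80% pool,
not experimental recording blocks. `randomSearch()` samples 50
hyperparameter configurations (F1 ∈ {4, 8, 16}, D ∈ {1, 2, 4},
F2 ∈ {8, 16, 32}, Adam or SGD+momentum, learning rate log-uniform on
[10⁻⁴, 10⁻²], weight decay log-uniform on [10⁻⁶, 10⁻³], and the
early-stop metric — ranges chosen here, as the original search space is
not published), trains each with three random initializations, and
selects by mean validation accuracy with deterministic tie-breaking.

The three subject-specific paradigms:

1. **Montage-specific** (`runMontageSpecific()`): one model per montage;
   the reported montage is chosen by *validation* accuracy only, before
   looking at its held-out test metrics.
2. **Cross-montage** (`runCrossMontage()`): one model on the pooled
   trials of all montages with label-and-montage stratified splits.
3. **Pre-train/fine-tune** (`runPretrainFinetune()`): pre-train on all
   montages except the target, then fine-tune *all* weights on the
   target montage's training split. Whether any layers should be frozen
   during fine-tuning is unstated in the source material; full-network
   fine-tuning is the default and the cap on fine-tuning epochs is
   configurable.

Weight decay is applied to convolution and dense weights only, not to
batch-norm parameters or the dense bias. A zero learning rate performs
no updates at all, so such a run is a pure evaluation. All fitting is
deterministic given the data, split and initialization seeds.

## Evaluation

`aurocScore()` is the Mann–Whitney estimate (midranks; ties count ½),
tested against the O(n²) pairwise oracle. `summarizeSubject()` averages
the five fold-models' held-out metrics and builds 95% confidence
intervals as mean ± t₀.₉₇₅,df=4 · SE — the t-based construction is this
package's choice of CI over fold metrics. Above-chance testing uses a
one-sided exact binomial test on the pooled held-out predictions
against 0.5 (the source material reports p < 0.05 without naming a
test); for AUROC a one-sided Wilcoxon rank-sum test is available when
pooled scores are supplied. `qualityAnova()` models accuracy ~ quality +
subject with Type-II (via `car::Anova`) or Type-I (sequential) sums of
squares, matching the two analyses the workflow calls for, and
`simulateQualityTable()` provides null and planted-effect tables for
its calibration. `aggregateExperiment()` produces the cross-subject
mean ± CI and above-chance counts for one cell of the input × band ×
paradigm grid.

## Feature attribution

`deepliftRescale()` implements DeepLIFT with the Rescale rule. Every
layer of this architecture is either linear in its input (convolutions,
inference-mode batch-norm, pooling, the dense head) or an elementwise
nonlinearity (ELU, sigmoid), so multipliers are the layer weights for
linear layers and Δout/Δin for the nonlinearities (local gradient when
Δin vanishes). Their composition satisfies summation-to-delta —
relevance sums to f(trial) − f(reference) — to floating-point precision,
which the tests assert at 10⁻³.

Choices fixed here: the reference input is the all-zero matrix, the
natural rest point of a scaled, baseline-corrected signal; relevance is
propagated all the way to the input voxel × time grid; and the sign
convention is with respect to the right-response direction of the
output (positive relevance pushes the prediction towards "right"),
regardless of the predicted class. `groupByConfidence()` partitions
trials into high (prediction < 0.20 or > 0.80) and low (between,
inclusive — "between" decides the boundary) confidence crossed with
response type; `meanHeatmap()` and `timeSlice()` produce the averaged
spatiotemporal maps and hemisphere-grid slices at chosen latencies
(nearest sample; 179 ms ↦ sample 35 at the default geometry).

## Worked example

A minimal planted-effect run (a single montage, strong effect, reduced
epochs so the chunk stays light):

```{r example, eval = FALSE}
cfg <- simConfig(nMontages = 1L, effectAmplitude = 3, noiseSd = 1, seed = 11)
ds <- generateSubjectDataset(cfg, "S1", modalities = "phase")
res <- runMontageSpecific(list(A = ds$A$phase),
                          tcfg = trainConfig(maxEpochs = 40L, patience = 10L,
                                             seed = 1),
                          seed = 5)
res$best$testAccuracy    # held-out accuracy, mean over the 5 fold models
```

## Problem sizes used by the tests and the acceptance script

The shipped checks run at deliberately modest sizes chosen as a
practical compromise for a single CPU: one synthetic montage of 240
trials at the full 42 × 56 geometry; up to 40 training epochs with
early stopping for recovery and localization runs; 10 permutation
seeds; 5 localization seeds; 200 ANOVA simulations per condition; and
20 random architectures for the accounting checks. These sizes are
stated here so results are interpreted at the scale they were computed.

## Known limitations

* The synthetic generator is the only data source; conclusions about
  real-data performance levels (e.g. specific accuracy percentages)
  cannot be drawn from it, and none are claimed.
* Voxel projection ignores diffusion-path weighting; montage geometry
  is abstract (no Talairach coordinates).
* The random search explores a package-chosen space, not the original
  (unpublished) one.
* Training is pure R; it is fast enough for the shipped problem sizes
  but not tuned for large-scale sweeps.
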