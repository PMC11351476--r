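# Metrics, confidence intervals, above-chance tests, cross-subject
# aggregation, and the data-quality ANOVA analyses.

#' Area under the ROC curve
#'
#' Mann-Whitney probability estimate: the probability that a randomly
#' chosen "right" trial is scored above a randomly chosen "left" trial,
#' with ties counting one half. Computed from midranks, equivalent to the
#' O(n^2) pairwise comparison.
#'
#' @param scores numeric classifier scores (higher = more "right").
#' @param labels per-trial labels; "right" is the positive class.
#' @return AUROC in [0, 1].
#' @examples
#' aurocScore(c(0.9, 0.8, 0.3, 0.1), c("right", "right", "left", "left"))
#' @export
aurocScore <- function(scores, labels) {
  labels <- factor(as.character(labels), levels = c("left", "right"))
  nPos <- sum(labels == "right")
  nNeg <- sum(labels == "left")
  if (nPos == 0L || nNeg == 0L)
    stop("both classes must be present to compute AUROC")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == "right"]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' Summarize a subject's cross-validated performance
#'
#' Mean and 95% confidence interval of the five fold-model test metrics
#' (t-based, df = folds - 1), plus above-chance flags and a one-sided
#' exact binomial p-value on the pooled held-out predictions against
#' chance level 0.5. With pooled scores and labels supplied, a one-sided
#' Wilcoxon rank-sum p-value for AUROC > 0.5 is added.
#'
#' @param foldMetrics data.frame with one row per fold and columns
#'   \code{testAccuracy}, \code{testAuroc}, \code{nTest}, \code{nCorrect}.
#' @param pooledScores,pooledLabels optional pooled held-out scores and
#'   labels across folds for the AUROC test.
#' @param conf confidence level.
#' @return list with means, CI bounds, above-chance flags and p-values.
#' @export
summarizeSubject <- function(foldMetrics, pooledScores = NULL,
                             pooledLabels = NULL, conf = 0.95) {
  k <- nrow(foldMetrics)
  ciOf <- function(x) {
    m <- mean(x)
    if (k < 2L) return(c(mean = m, lo = NA_real_, hi = NA_real_))
    se <- stats::sd(x) / sqrt(k)
    tq <- stats::qt(1 - (1 - conf) / 2, df = k - 1L)
    c(mean = m, lo = m - tq * se, hi = m + tq * se)
  }
  acc <- ciOf(foldMetrics$testAccuracy)
  auc <- ciOf(foldMetrics$testAuroc)
  nPooled <- sum(foldMetrics$nTest)
  nCorrect <- sum(foldMetrics$nCorrect)
  pAcc <- if (nPooled > 0)
    stats::binom.test(nCorrect, nPooled, p = 0.5,
                      alternative = "greater")$p.value else NA_real_
  pAuc <- if (!is.null(pooledScores) && !is.null(pooledLabels)) {
    pooledLabels <- factor(as.character(pooledLabels),
                           levels = c("left", "right"))
    stats::wilcox.test(pooledScores[pooledLabels == "right"],
                       pooledScores[pooledLabels == "left"],
                       alternative = "greater", exact = FALSE)$p.value
  } else NA_real_
  list(nFolds = k,
       accuracy = unname(acc[1L]), accuracyCI = unname(acc[2:3]),
       auroc = unname(auc[1L]), aurocCI = unname(auc[2:3]),
       aboveChanceAccuracy = unname(acc[1L]) > 0.5,
       aboveChanceAuroc = unname(auc[1L]) > 0.5,
       pAccuracy = pAcc, pAuroc = pAuc,
       nPooled = nPooled, nCorrect = nCorrect)
}

#' Montage data-quality table
#'
#' One row per (subject, montage): viable voxel counts (total and per
#' hemisphere), mean channels per viable voxel, and the montage's
#' held-out test accuracy.
#'
#' @param entries list of lists with elements \code{subject},
#'   \code{montage} (a \linkS4class{MontageSpec}) and \code{accuracy}.
#' @param C flattened voxel count (for the hemisphere split).
#' @return data.frame.
#' @export
qualityTable <- function(entries, C = 42L) {
  half <- C %/% 2L
  do.call(rbind, lapply(entries, function(e) {
    mask <- viableVoxels(e$montage)
    k <- channelsPerVoxel(e$montage)
    data.frame(subject = e$subject, montage = e$montage@montageId,
               viableVoxels = sum(mask),
               viableVoxelsLeft = sum(mask[seq_len(half)]),
               viableVoxelsRight = sum(mask[half + seq_len(half)]),
               channelsPerViableVoxel = mean(k[mask]),
               accuracy = e$accuracy)
  }))
}

#' Data-quality ANOVA
#'
#' Models held-out classification accuracy as a linear function of one
#' data-quality measure with subject as a factor
#' (\code{accuracy ~ quality + subject}) and returns the quality
#' effect's F statistic and p-value under Type-II (order-invariant,
#' via \code{car::Anova}) or Type-I (sequential) sums of squares.
#'
#' @param table data.frame with columns \code{accuracy}, \code{subject},
#'   and the quality measure.
#' @param qualityMeasure column name of the quality measure.
#' @param anovaType "II" or "I".
#' @return list with the full ANOVA \code{table}, and the quality
#'   effect's \code{F} and \code{p}.
#' @export
qualityAnova <- function(table, qualityMeasure = "channelsPerViableVoxel",
                         anovaType = c("II", "I")) {
  anovaType <- match.arg(anovaType)
  if (!qualityMeasure %in% names(table))
    stop("quality measure not in table: ", qualityMeasure)
  if (length(unique(table$subject)) < 2L)
    stop("at least 2 subjects required")
  df <- data.frame(accuracy = table$accuracy,
                   quality = table[[qualityMeasure]],
                   subject = factor(table$subject))
  if (stats::var(df$quality) == 0)
    stop("rank-deficient design: quality measure is constant")
  fit <- stats::lm(accuracy ~ quality + subject, data = df)
  if (anovaType == "II") {
    tab <- car::Anova(fit, type = "II")
    list(table = tab, F = tab["quality", "F value"],
         p = tab["quality", "Pr(>F)"])
  } else {
    tab <- stats::anova(fit)
    list(table = tab, F = tab["quality", "F value"],
         p = tab["quality", "Pr(>F)"])
  }
}

#' Simulate a data-quality table
#'
#' Generates (subject, montage) rows where accuracy is subject baseline
#' plus \code{slope} times a standardized quality measure plus Gaussian
#' noise; \code{slope = 0} gives the null of no quality effect. Used to
#' calibrate and power-check \code{\link{qualityAnova}}.
#'
#' @param nSubjects,nMontages table dimensions.
#' @param slope accuracy change per SD of quality.
#' @param noiseSd residual SD of accuracy.
#' @param seed RNG seed.
#' @return data.frame suitable for \code{\link{qualityAnova}} (quality
#'   column \code{channelsPerViableVoxel}).
#' @export
simulateQualityTable <- function(nSubjects = 12L, nMontages = 4L,
                                 slope = 0, noiseSd = 0.05, seed = 1L) {
  withSeed(seed, {
    n <- nSubjects * nMontages
    subject <- rep(paste0("S", seq_len(nSubjects)), each = nMontages)
    base <- rep(stats::rnorm(nSubjects, 0.6, 0.03), each = nMontages)
    quality <- stats::rnorm(n)
    acc <- base + slope * quality + stats::rnorm(n, sd = noiseSd)
    data.frame(subject = subject,
               montage = rep(LETTERS[seq_len(nMontages)], nSubjects),
               channelsPerViableVoxel = quality, accuracy = acc)
  })
}

#' Aggregate per-subject summaries across an experimental grid cell
#'
#' Cross-subject mean and t-based 95% confidence interval of accuracy and
#' AUROC for one (input signal, frequency band, training paradigm)
#' configuration, with counts of subjects above chance.
#'
#' @param summaries list of per-subject summaries from
#'   \code{\link{summarizeSubject}}.
#' @param conf confidence level.
#' @return one-row data.frame: means, CI half-widths, above-chance
#'   counts and subject count.
#' @export
aggregateExperiment <- function(summaries, conf = 0.95) {
  acc <- vapply(summaries, `[[`, numeric(1), "accuracy")
  auc <- vapply(summaries, `[[`, numeric(1), "auroc")
  n <- length(summaries)
  hw <- function(x) {
    if (n < 2L) return(NA_real_)
    stats::qt(1 - (1 - conf) / 2, df = n - 1L) * stats::sd(x) / sqrt(n)
  }
  data.frame(
    nSubjects = n,
    accuracy = mean(acc), accuracyCI = hw(acc),
    auroc = mean(auc), aurocCI = hw(auc),
    nAboveChanceAccuracy = sum(vapply(summaries, `[[`, logical(1),
                                      "aboveChanceAccuracy")),
    nAboveChanceAuroc = sum(vapply(summaries, `[[`, logical(1),
                                   "aboveChanceAuroc")))
}
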