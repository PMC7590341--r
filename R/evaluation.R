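#' Empirical ROC curve, AUC and optimal screening threshold
#'
#' Operating points are evaluated at every unique score (flag = score >=
#' threshold) plus the flag-everything (-Inf) and flag-nothing (+Inf)
#' limits. The AUC is the Mann-Whitney pair count over all positive x
#' negative score pairs, with ties counting one half -- exactly the
#' trapezoid area under the empirical curve, but directly auditable against
#' a brute-force oracle. The optimal screening threshold follows the
#' screening rule appropriate to a triage method where false negatives are
#' unacceptable: among thresholds with sensitivity exactly 1.0 on the
#' cohort, the one with maximal specificity.
#'
#' @param cohort a [LabeledCohort-class] with at least one positive and one
#'   negative sample
#' @return a [RocResult-class].
#' @examples
#' c <- labeledCohort(1:4, c(10, 9, 1, 2), c(800, 700, 0, 100))
#' auc(empiricalRoc(c))  # 1
#' @export
empiricalRoc <- function(cohort) {
  stopifnot(is(cohort, "LabeledCohort"))
  pos <- positiveLabels(cohort)
  if (!any(pos) || all(pos))
    stop("degenerate labels: need at least one positive and one negative")
  sPos <- cohort@sumScore[pos]
  sNeg <- cohort@sumScore[!pos]
  nPos <- length(sPos); nNeg <- length(sNeg)
  # Mann-Whitney pair count, ties = 1/2
  wins <- sum(outer(sPos, sNeg, ">")) + 0.5 * sum(outer(sPos, sNeg, "=="))
  aucVal <- wins / (nPos * nNeg)
  thresholds <- c(-Inf, sort(unique(cohort@sumScore)), Inf)
  sens <- vapply(thresholds, function(t) mean(sPos >= t), numeric(1L))
  spec <- vapply(thresholds, function(t) mean(sNeg < t), numeric(1L))
  full <- sens == 1
  opt <- thresholds[full][which.max(spec[full])]
  new("RocResult",
      points = data.frame(threshold = thresholds, sensitivity = sens,
                          specificity = spec),
      auc = aucVal, optimalThreshold = opt,
      nPos = nPos, nNeg = nNeg)
}

#' Confusion counts and rates at a screening threshold
#'
#' @param cohort a [LabeledCohort-class]
#' @param threshold summed-Z-ratio cutoff
#' @param inclusive flag = score >= threshold (default) or > threshold
#' @return list with sensitivity, specificity and the tp/fp/tn/fn counts.
#'   A single-class cohort returns `NA` for the undefined rate.
#' @export
confusionAtThreshold <- function(cohort, threshold, inclusive = TRUE) {
  stopifnot(is(cohort, "LabeledCohort"))
  pos <- positiveLabels(cohort)
  flag <- if (inclusive) cohort@sumScore >= threshold
          else cohort@sumScore > threshold
  tp <- sum(flag & pos); fn <- sum(!flag & pos)
  fp <- sum(flag & !pos); tn <- sum(!flag & !pos)
  list(sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
       specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

#' Pearson correlation between screening score and HPLC concentration
#'
#' @param cohort a [LabeledCohort-class] with at least 3 entries and
#'   non-zero variance in both columns
#' @return product-moment correlation coefficient in [-1, 1].
#' @export
pearsonCorrelation <- function(cohort) {
  stopifnot(is(cohort, "LabeledCohort"))
  if (length(cohort) < 3L) stop("need at least 3 entries")
  if (var(cohort@sumScore) == 0 || var(cohort@hplcPpm) == 0)
    stop("degenerate cohort: zero variance")
  cor(cohort@sumScore, cohort@hplcPpm)
}

#' Bootstrap simulation of screening triage risk
#'
#' Nonparametric bootstrap of the labeled cohort: each iteration resamples
#' the cohort with replacement (same size), applies the screening
#' threshold, and records (i) the false-negative rate among the resample's
#' true positives and (ii) the triage (flag) fraction among its sub-limit
#' samples. Iterations whose resample contains no sample of the relevant
#' class leave that rate undefined; such iterations are excluded from the
#' mean and quantiles of that rate. Means and 2.5/50/97.5% quantiles are
#' reported; the run is fully determined by the seed.
#'
#' @param cohort a [LabeledCohort-class]
#' @param threshold screening cutoff on the summed Z-ratio
#' @param nIter number of bootstrap iterations (the study design uses
#'   10,000)
#' @param seed RNG seed; recorded in the result
#' @param inclusive flag = score >= threshold (default) or > threshold
#' @return a [MonteCarloResult-class].
#' @export
monteCarloTriage <- function(cohort, threshold = 5, nIter = 10000L,
                             seed = 1L, inclusive = TRUE) {
  stopifnot(is(cohort, "LabeledCohort"), nIter >= 1L)
  n <- length(cohort)
  pos <- positiveLabels(cohort)
  flag <- if (inclusive) cohort@sumScore >= threshold
          else cohort@sumScore > threshold
  rng <- local({
    set.seed(seed)
    matrix(sample.int(n, n * nIter, replace = TRUE), nrow = nIter)
  })
  fnRates <- numeric(nIter)
  fpRates <- numeric(nIter)
  for (i in seq_len(nIter)) {
    idx <- rng[i, ]
    p <- pos[idx]; f <- flag[idx]
    fnRates[i] <- if (any(p)) mean(!f[p]) else NA_real_
    fpRates[i] <- if (any(!p)) mean(f[!p]) else NA_real_
  }
  q <- c(0.025, 0.5, 0.975)
  new("MonteCarloResult", nIter = as.integer(nIter), seed = as.integer(seed),
      fnRateMean = mean(fnRates, na.rm = TRUE),
      fpTriageMean = mean(fpRates, na.rm = TRUE),
      fnRateQuantiles = quantile(fnRates, q, na.rm = TRUE, names = TRUE),
      fpTriageQuantiles = quantile(fpRates, q, na.rm = TRUE, names = TRUE))
}
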