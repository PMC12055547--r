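# Confusion-matrix metric suite and paired significance tests. Metrics are
# computed from explicit one-vs-rest confusion counts: precision, sensitivity
# (recall), specificity, NPV, F-measure, Jaccard and MCC per class and
# macro-averaged; accuracy is pooled; FPR / FNR are the per-class complements
# of specificity / sensitivity averaged across classes; Hamming loss for
# single-label multiclass prediction is the misclassification rate.

#' One-vs-rest confusion counts
#'
#' @param yTrue,yPred equal-length 0-based integer label vectors.
#' @param nClasses number of classes (labels must be `< nClasses`).
#' @return a `confusionCounts`: per-class `tp`, `fp`, `fn`, `tn` vectors, the
#'   full multiclass `table`, `nClasses`, `nSamples`.
#' @export
confusionCounts <- function(yTrue, yPred, nClasses) {
  if (length(yTrue) != length(yPred))
    stop(sprintf("length mismatch: %d true vs %d predicted labels",
                 length(yTrue), length(yPred)), call. = FALSE)
  if (length(yTrue) == 0L) stopParam("yTrue", "empty input")
  nClasses <- checkCount(nClasses, "nClasses", min = 2L)
  if (any(yTrue < 0 | yTrue >= nClasses | yPred < 0 | yPred >= nClasses))
    stopParam("yTrue", "labels must lie in [0, nClasses)")
  n <- length(yTrue)
  tab <- matrix(0L, nClasses, nClasses)  # rows = true, cols = predicted
  for (i in seq_len(n)) tab[yTrue[i] + 1L, yPred[i] + 1L] <- tab[yTrue[i] + 1L, yPred[i] + 1L] + 1L
  tp <- diag(tab)
  fn <- rowSums(tab) - tp
  fp <- colSums(tab) - tp
  tn <- n - tp - fn - fp
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, table = tab,
                 nClasses = nClasses, nSamples = n),
            class = "confusionCounts")
}

safeDiv <- function(num, den) ifelse(den == 0, 0, num / den)

#' Classification metric report
#'
#' Per class (one-vs-rest): precision TP/(TP+FP), sensitivity TP/(TP+FN),
#' specificity TN/(TN+FP), NPV TN/(TN+FN), F = 2PR/(P+R),
#' Jaccard TP/(TP+FP+FN), MCC = (TP TN - FP FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN));
#' all macro-averaged. Accuracy is pooled correct / n; Hamming loss is
#' 1 - accuracy; FPR = 1 - specificity and FNR = 1 - sensitivity per class
#' before averaging. Any 0/0 cell contributes 0 and raises a flag.
#'
#' @param counts a [confusionCounts()].
#' @return a `metricReport` list of scalar metrics plus `perClass`.
#' @export
metricReport <- function(counts) {
  if (!inherits(counts, "confusionCounts")) stopParam("counts", "must come from confusionCounts()")
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  flags <- character(0)
  if (any(tp + fp == 0) || any(tp + fn == 0) || any(tn + fn == 0))
    flags <- "degenerate_denominator"
  precision <- safeDiv(tp, tp + fp)
  sensitivity <- safeDiv(tp, tp + fn)
  specificity <- safeDiv(tn, tn + fp)
  npv <- safeDiv(tn, tn + fn)
  f <- safeDiv(2 * precision * sensitivity, precision + sensitivity)
  jaccard <- safeDiv(tp, tp + fp + fn)
  mccDen <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- safeDiv(tp * tn - fp * fn, mccDen)
  accuracy <- sum(tp) / counts$nSamples  # pooled micro accuracy
  perClass <- data.frame(class = seq_len(counts$nClasses) - 1L,
                         precision = precision, sensitivity = sensitivity,
                         specificity = specificity, npv = npv,
                         f_measure = f, jaccard = jaccard, mcc = mcc,
                         fpr = 1 - specificity, fnr = 1 - sensitivity)
  out <- list(accuracy = accuracy,
              precision = mean(precision),
              sensitivity = mean(sensitivity),
              specificity = mean(specificity),
              f_measure = mean(f),
              mcc = mean(mcc),
              npv = mean(npv),
              fpr = mean(1 - specificity),
              fnr = mean(1 - sensitivity),
              jaccard = mean(jaccard),
              hamming_loss = 1 - accuracy,
              averaging = "macro",
              perClass = perClass)
  class(out) <- "metricReport"
  setFlags(out, flags)
}

#' @export
print.metricReport <- function(x, ...) {
  keys <- c("accuracy", "precision", "sensitivity", "specificity", "f_measure",
            "mcc", "npv", "fpr", "fnr", "jaccard", "hamming_loss")
  vals <- vapply(keys, function(k) x[[k]], numeric(1))
  cat("metricReport (macro-averaged over classes):\n")
  for (k in keys) cat(sprintf("  %-12s %.6f\n", k, x[[k]]))
  invisible(x)
}

#' Evaluate a model on held-out features
#'
#' @param model a `cardioModel`.
#' @param features a [cohortFeatures()] or `list(inputs, labels)`.
#' @return a [metricReport()].
#' @export
evaluateModel <- function(model, features) {
  fi <- featuresInputs(features)
  pred <- classify(model, fi$inputs)
  metricReport(confusionCounts(fi$labels, pred, fi$nClasses))
}

#' Paired t-test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with the sample (n - 1) standard
#' deviation of the paired differences; two-sided p from the Student t
#' distribution with n - 1 degrees of freedom.
#'
#' @param scoresA,scoresB equal-length paired score vectors (n >= 5).
#' @return list with `t`, `p`, `df`, `degenerate` (TRUE with a flag when all
#'   differences are equal, i.e. sd = 0).
#' @export
pairedTTest <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB))
    stopParam("scoresB", "length mismatch with scoresA")
  n <- length(scoresA)
  if (n < 5L) stopParam("scoresA", "need at least 5 pairs")
  d <- scoresA - scoresB
  s <- sd(d)
  if (s == 0) {
    out <- list(t = NA_real_, p = NA_real_, df = n - 1L, degenerate = TRUE)
    return(setFlags(out, "zero_variance_differences"))
  }
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), df = n - 1L), df = n - 1L, degenerate = FALSE)
}

#' Wilcoxon signed-rank test (normal approximation)
#'
#' Zero differences are excluded; ties get mid-ranks; the z statistic uses
#' the normal approximation with tie-corrected variance and a 0.5 continuity
#' correction toward the null mean.
#'
#' @param scoresA,scoresB equal-length paired score vectors (>= 10 non-zero
#'   differences recommended for the approximation).
#' @return list with `z`, `p` (two-sided), `wPlus` (positive-rank sum),
#'   `nEffective`, `degenerate`.
#' @export
wilcoxonSignedRank <- function(scoresA, scoresB) {
  if (length(scoresA) != length(scoresB))
    stopParam("scoresB", "length mismatch with scoresA")
  d <- scoresA - scoresB
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) {
    out <- list(z = NA_real_, p = NA_real_, wPlus = NA_real_,
                nEffective = 0L, degenerate = TRUE)
    return(setFlags(out, "all_differences_zero"))
  }
  r <- rank(abs(d))  # mid-ranks for ties
  wPlus <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  tieCounts <- table(r)
  tieAdj <- sum(tieCounts^3 - tieCounts) / 48
  sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24 - tieAdj)
  if (sigma == 0) {
    out <- list(z = NA_real_, p = NA_real_, wPlus = wPlus,
                nEffective = n, degenerate = TRUE)
    return(setFlags(out, "zero_variance"))
  }
  cc <- sign(wPlus - mu) * 0.5  # continuity correction toward the mean
  z <- (wPlus - mu - cc) / sigma
  list(z = z, p = 2 * pnorm(-abs(z)), wPlus = wPlus, nEffective = n,
       degenerate = FALSE)
}
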