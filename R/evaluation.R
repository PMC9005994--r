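# Evaluation: confusion counts, scalar metrics, ROC / PR curves,
# FPR-matched thresholds.

#' Confusion counts at a decision threshold
#'
#' A segment is called positive when its score is greater than or equal
#' to the threshold (so a score exactly at the threshold is a positive
#' call).
#'
#' @param yTrue Binary 0/1 labels.
#' @param scores Scores in [0, 1].
#' @param threshold Decision threshold (default 0.5).
#' @return Named integer vector TP, FP, TN, FN.
#' @export
confusionCounts <- function(yTrue, scores, threshold = 0.5) {
  yTrue <- .assertBinaryLabels(yTrue)
  if (!length(yTrue)) stop("empty input")
  if (length(scores) != length(yTrue))
    stop("scores and labels must have equal length")
  pred <- scores >= threshold
  c(TP = sum(pred & yTrue == 1L),
    FP = sum(pred & yTrue == 0L),
    TN = sum(!pred & yTrue == 0L),
    FN = sum(!pred & yTrue == 1L))
}

#' Scalar classification metrics from confusion counts
#'
#' Sen = TP/(TP+FN), Spe = TN/(TN+FP), Pre = TP/(TP+FP),
#' Acc = (TP+TN)/total, F1 = 2TP/(2TP+FP+FN),
#' MCC = (TN*TP - FN*FP)/sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN)),
#' FOR = FN/(FN+TN).  Zero-denominator conventions: Pre = 0 when
#' TP+FP = 0; MCC = 0 when any factor of its denominator is 0; FOR = 0
#' when FN+TN = 0.
#'
#' @param counts Named vector with TP, FP, TN, FN.
#' @return Named numeric vector Sen, Spe, Pre, Acc, F1, MCC, FOR.
#' @export
classificationMetrics <- function(counts) {
  TP <- as.numeric(counts[["TP"]]); FP <- as.numeric(counts[["FP"]])
  TN <- as.numeric(counts[["TN"]]); FN <- as.numeric(counts[["FN"]])
  sen <- if (TP + FN > 0) TP / (TP + FN) else 0
  spe <- if (TN + FP > 0) TN / (TN + FP) else 0
  pre <- if (TP + FP > 0) TP / (TP + FP) else 0
  acc <- (TP + TN) / (TP + FP + TN + FN)
  f1 <- if (2 * TP + FP + FN > 0) 2 * TP / (2 * TP + FP + FN) else 0
  den <- (TP + FP) * (TP + FN) * (TN + FP) * (TN + FN)
  mcc <- if (den > 0) (TN * TP - FN * FP) / sqrt(den) else 0
  for_ <- if (FN + TN > 0) FN / (FN + TN) else 0
  c(Sen = sen, Spe = spe, Pre = pre, Acc = acc, F1 = f1, MCC = mcc,
    FOR = for_)
}

#' ROC curve and AUROC
#'
#' Points are computed at every distinct score cut; the area (by the
#' trapezoidal rule) equals the Mann-Whitney statistic: the fraction of
#' (positive, negative) pairs in which the positive scores higher, ties
#' counted one half.
#'
#' @param yTrue Binary 0/1 labels (both classes required).
#' @param scores Numeric scores.
#' @return List with `points` (data.frame fpr, tpr) and `auc`.
#' @export
rocCurve <- function(yTrue, scores) {
  yTrue <- .assertBinaryLabels(yTrue)
  nP <- sum(yTrue == 1L); nN <- sum(yTrue == 0L)
  if (nP == 0L || nN == 0L) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  y <- yTrue[ord]; s <- scores[ord]
  cumTP <- cumsum(y == 1L)
  cumFP <- cumsum(y == 0L)
  last <- c(s[-1] != s[-length(s)], TRUE)  # end of each tie group
  tpr <- c(0, cumTP[last] / nP)
  fpr <- c(0, cumFP[last] / nN)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall curve and AUPRC
#'
#' Points at every distinct score cut; the area uses the step-wise
#' summation standard for PR curves (sum over cuts of
#' (recall_i - recall_{i-1}) * precision_i), not trapezoids.
#'
#' @param yTrue Binary 0/1 labels (at least one positive required).
#' @param scores Numeric scores.
#' @return List with `points` (data.frame recall, precision) and `auc`.
#' @export
prCurve <- function(yTrue, scores) {
  yTrue <- .assertBinaryLabels(yTrue)
  nP <- sum(yTrue == 1L)
  if (nP == 0L) stop("at least one positive is required")
  ord <- order(scores, decreasing = TRUE)
  y <- yTrue[ord]; s <- scores[ord]
  cumTP <- cumsum(y == 1L)
  k <- seq_along(y)
  last <- c(s[-1] != s[-length(s)], TRUE)
  rec <- cumTP[last] / nP
  prec <- cumTP[last] / k[last]
  auc <- sum(diff(c(0, rec)) * prec)
  list(points = data.frame(recall = rec, precision = prec), auc = auc)
}

#' Smallest threshold with empirical FPR at or below a target
#'
#' @param yTrue Binary 0/1 labels (negatives required).
#' @param scores Numeric scores.
#' @param targetFpr Target false-positive rate in (0, 1].
#' @return The smallest threshold t such that the fraction of negatives
#'   scoring >= t is at most `targetFpr`.
#' @export
thresholdForFpr <- function(yTrue, scores, targetFpr) {
  yTrue <- .assertBinaryLabels(yTrue)
  if (targetFpr <= 0 || targetFpr > 1)
    stop("targetFpr must be in (0, 1]")
  neg <- scores[yTrue == 0L]
  if (!length(neg)) stop("negatives are required")
  cand <- sort(unique(scores))
  for (t in cand) {
    if (mean(neg >= t) <= targetFpr) return(t)
  }
  max(scores) + 1e-9
}

#' Full evaluation of scores against labels
#'
#' @param yTrue Binary 0/1 labels.
#' @param scores Scores in [0, 1].
#' @param threshold Decision threshold for the confusion counts.
#' @return A [MetricsReport-class].
#' @export
evaluateScores <- function(yTrue, scores, threshold = 0.5) {
  counts <- confusionCounts(yTrue, scores, threshold)
  roc <- rocCurve(yTrue, scores)
  prc <- prCurve(yTrue, scores)
  new("MetricsReport",
      counts = counts,
      metrics = classificationMetrics(counts),
      auroc = roc$auc, auprc = prc$auc,
      rocPoints = roc$points, prcPoints = prc$points,
      threshold = threshold)
}

#' @describeIn MetricsReport-class Scalar metrics plus areas.
#' @param x,object A `MetricsReport`.
#' @export
setMethod("metricValues", "MetricsReport", function(x)
  c(x@metrics, AUROC = x@auroc, AUPRC = x@auprc))

#' @describeIn MetricsReport-class Confusion counts.
#' @export
setMethod("confusionValues", "MetricsReport", function(x) x@counts)

#' @describeIn MetricsReport-class Display a summary.
#' @export
setMethod("show", "MetricsReport", function(object) {
  cat("MetricsReport (threshold =", object@threshold, ")\n")
  cat("  counts: TP =", object@counts[["TP"]],
      "FP =", object@counts[["FP"]],
      "TN =", object@counts[["TN"]],
      "FN =", object@counts[["FN"]], "\n")
  m <- object@metrics
  cat(sprintf(
    "  Sen %.3f  Spe %.3f  Pre %.3f  Acc %.3f  F1 %.3f  MCC %.3f  FOR %.3f\n",
    m[["Sen"]], m[["Spe"]], m[["Pre"]], m[["Acc"]], m[["F1"]],
    m[["MCC"]], m[["FOR"]]))
  cat(sprintf("  AUROC %.4f  AUPRC %.4f\n", object@auroc, object@auprc))
})

#' Write a MetricsReport as JSON (plus optional curve TSVs)
#'
#' @param x A [MetricsReport-class].
#' @param path JSON path.
#' @param curves Also write `<path>.roc.tsv` / `<path>.prc.tsv`.
#' @return `path`, invisibly.
#' @export
writeMetricsReport <- function(x, path, curves = FALSE) {
  jsonlite::write_json(
    list(threshold = x@threshold, counts = as.list(x@counts),
         metrics = as.list(x@metrics), auroc = x@auroc,
         auprc = x@auprc),
    path, auto_unbox = TRUE, digits = NA)
  if (curves) {
    utils::write.table(x@rocPoints, paste0(path, ".roc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(x@prcPoints, paste0(path, ".prc.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
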