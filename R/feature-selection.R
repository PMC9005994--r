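# Feature ranking (SHAP / F-score / mRMR) and incremental selection.

.resolveXy <- function(X, y) {
  if (is(X, "FeatureMatrix")) {
    if (missing(y) || is.null(y)) y <- segmentLabels(X)
    X <- featureValues(X)
  }
  X <- .assertFiniteMatrix(X)
  y <- .assertBinaryLabels(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)")
  if (length(table(y)) < 2L || min(table(y)) < 2L)
    stop("both classes need at least 2 samples")
  list(X = X, y = y)
}

.newRanking <- function(method, names, scores, provenance) {
  new("FeatureRanking", method = method, orderedNames = names,
      scores = scores, provenance = provenance)
}

#' @describeIn FeatureRanking-class Feature names, best first.
#' @param x,object A `FeatureRanking`.
#' @export
setMethod("rankedFeatures", "FeatureRanking", function(x) x@orderedNames)

#' @describeIn FeatureRanking-class Scores aligned with [rankedFeatures()].
#' @export
setMethod("rankingScores", "FeatureRanking", function(x)
  stats::setNames(x@scores, x@orderedNames))

#' @describeIn FeatureRanking-class The ranking method.
#' @export
setMethod("rankingMethod", "FeatureRanking", function(x) x@method)

#' @describeIn FeatureRanking-class Display a summary.
#' @export
setMethod("show", "FeatureRanking", function(object) {
  cat("FeatureRanking (", object@method, "): ",
      length(object@orderedNames), " features\n", sep = "")
  k <- min(5L, length(object@orderedNames))
  if (k) {
    cat("  top:", paste(sprintf("%s (%.4g)", object@orderedNames[1:k],
                                object@scores[1:k]), collapse = ", "),
        "\n")
  }
})

#' Write / read a FeatureRanking as two-column TSV (name, score)
#'
#' @param x A [FeatureRanking-class].
#' @param path TSV path.
#' @param method Ranking method of the file being read.
#' @return `path` invisibly / a [FeatureRanking-class].
#' @export
writeRanking <- function(x, path) {
  utils::write.table(
    data.frame(name = x@orderedNames, score = x@scores),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRanking
#' @export
readRanking <- function(path, method = c("shap", "fscore", "mrmr")) {
  method <- match.arg(method)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  .newRanking(method, df$name, df$score, list(source = path))
}

#' Rank features by mean absolute Shapley attribution
#'
#' Fits a gradient-boosted tree ensemble on the full matrix, computes
#' each training row's exact per-feature Shapley attributions with the
#' tree-path-dependent algorithm, and scores every feature by the mean
#' absolute attribution over the training rows.  The ranking model's
#' hyperparameters are fixed and independent of any later per-dataset
#' tuning, since ranking precedes hyperparameter search in the pipeline.
#'
#' @param X A [FeatureMatrix-class] or numeric matrix (rows = segments).
#' @param y Binary labels (taken from `X` when it is a FeatureMatrix).
#' @param params Ranking-model hyperparameters: `max_depth`, `eta`,
#'   `nrounds`.
#' @param seed Seed for the fit.
#' @return A [FeatureRanking-class] with method `"shap"`.
#' @export
rankByShap <- function(X, y = NULL,
                       params = list(max_depth = 6, eta = 0.1,
                                     nrounds = 500),
                       seed = 1L) {
  d <- .resolveXy(X, y)
  fit <- .fitXGB(d$X, d$y, params, seed = seed)
  contrib <- predict(fit, xgboost::xgb.DMatrix(d$X), predcontrib = TRUE)
  imp <- colMeans(abs(contrib[, colnames(d$X), drop = FALSE]))
  ord <- order(-imp, seq_along(imp))
  .newRanking("shap", colnames(d$X)[ord], unname(imp[ord]),
              list(params = params, seed = seed))
}

#' Rank features by F-score
#'
#' For each feature the F-score is the squared separation of the class
#' means from the grand mean divided by the sum of the within-class
#' sample variances (n-1 denominators).  A feature with zero within-class
#' variance in both classes but separated means receives an infinite
#' score and ranks first.
#'
#' @inheritParams rankByShap
#' @return A [FeatureRanking-class] with method `"fscore"`.
#' @export
rankByFscore <- function(X, y = NULL) {
  d <- .resolveXy(X, y)
  s <- featureFscores(d$X, d$y)
  ord <- order(-s, seq_along(s))
  .newRanking("fscore", colnames(d$X)[ord], unname(s[ord]), list())
}

#' Per-feature F-scores
#'
#' @param X Numeric matrix (rows = samples).
#' @param y Binary 0/1 labels.
#' @return Named numeric vector of F-scores.
#' @export
featureFscores <- function(X, y) {
  X <- .assertFiniteMatrix(X)
  y <- .assertBinaryLabels(y)
  Xp <- X[y == 1L, , drop = FALSE]
  Xn <- X[y == 0L, , drop = FALSE]
  mAll <- colMeans(X)
  mP <- colMeans(Xp)
  mN <- colMeans(Xn)
  vP <- apply(Xp, 2, stats::var)
  vN <- apply(Xn, 2, stats::var)
  num <- (mP - mAll)^2 + (mN - mAll)^2
  den <- vP + vN
  s <- ifelse(den > 0, num / den, ifelse(num > 0, Inf, 0))
  stats::setNames(s, colnames(X))
}

# equal-frequency discretization for mutual information; features with
# few distinct values are used as categories directly so tied values
# never split across bins
.discretize <- function(x, bins = 5L) {
  ux <- unique(x)
  if (length(ux) <= bins) return(match(x, sort(ux)))
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = bins + 1)))
  if (length(br) < 3L) return(match(x, sort(ux)))
  as.integer(cut(x, breaks = br, include.lowest = TRUE))
}

#' Empirical mutual information between two discrete vectors
#'
#' Computed in nats from the joint histogram.
#'
#' @param a,b Integer/factor vectors of equal length.
#' @return Mutual information in nats.
#' @export
mutualInformation <- function(a, b) {
  a <- as.integer(factor(a))
  b <- as.integer(factor(b))
  na <- max(a); nb <- max(b)
  # column-major joint layout matching outer(pa, pb)
  joint <- tabulate(a + (b - 1L) * na, nbins = na * nb) / length(a)
  pa <- tabulate(a, nbins = na) / length(a)
  pb <- tabulate(b, nbins = nb) / length(b)
  pab <- outer(pa, pb)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / pab[nz]))
}

#' Rank features by minimum-redundancy maximum-relevance (mRMR)
#'
#' Features are discretized (equal-frequency binning, features with few
#' distinct values used as categories directly) and selected greedily:
#' the first pick maximizes mutual information with the label; each
#' subsequent pick maximizes relevance minus the mean mutual information
#' with the already-selected set.  Features beyond `nSelect` are appended
#' in relevance order with `NA` scores so the ranking remains a
#' permutation of all columns.
#'
#' @inheritParams rankByShap
#' @param nSelect Number of features selected greedily (default 50).
#' @param bins Discretization bins (default 5).
#' @return A [FeatureRanking-class] with method `"mrmr"`; scores are the
#'   selection-step criterion values.
#' @export
rankByMrmr <- function(X, y = NULL, nSelect = 50L, bins = 5L) {
  d <- .resolveXy(X, y)
  p <- ncol(d$X)
  nSelect <- min(as.integer(nSelect), p)
  D <- apply(d$X, 2, .discretize, bins = bins)
  rel <- vapply(seq_len(p), function(j) mutualInformation(D[, j], d$y),
                0)
  selected <- integer(0)
  scores <- numeric(0)
  redSum <- numeric(p)  # sum of MI(candidate, selected)
  remaining <- seq_len(p)
  for (step in seq_len(nSelect)) {
    crit <- if (length(selected) == 0L) rel[remaining] else
      rel[remaining] - redSum[remaining] / length(selected)
    pick <- remaining[order(-crit, remaining)[1]]
    scores <- c(scores, max(crit))
    selected <- c(selected, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining))
      redSum[remaining] <- redSum[remaining] +
        vapply(remaining, function(j)
          mutualInformation(D[, j], D[, pick]), 0)
  }
  rest <- remaining[order(-rel[remaining], remaining)]
  .newRanking("mrmr",
              colnames(d$X)[c(selected, rest)],
              c(scores, rep(NA_real_, length(rest))),
              list(nSelect = nSelect, bins = bins))
}

#' @describeIn SelectionResult-class The (n, mean CV AUROC) curve.
#' @param x,object A `SelectionResult`.
#' @export
setMethod("selectionCurve", "SelectionResult", function(x) x@curve)

#' @describeIn SelectionResult-class Optimal subset size.
#' @export
setMethod("bestN", "SelectionResult", function(x) x@bestN)

#' @describeIn SelectionResult-class AUROC at the optimal subset size.
#' @export
setMethod("bestAUROC", "SelectionResult", function(x) x@bestAUROC)

#' @describeIn SelectionResult-class Names of the selected features.
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x)
  x@selectedNames)

#' @describeIn SelectionResult-class Display a summary.
#' @export
setMethod("show", "SelectionResult", function(object) {
  cat("SelectionResult:", nrow(object@curve), "subset sizes evaluated\n")
  cat(sprintf("  best n = %d with mean CV AUROC = %.4f\n",
              object@bestN, object@bestAUROC))
})

#' Default subset-size grid for incremental selection
#'
#' Steps of 4 up to 300, then steps of 20 up to the feature count.
#'
#' @param p Total number of features (default 808).
#' @return Integer vector of subset sizes.
#' @export
ifsGrid <- function(p = 808L) {
  g <- c(seq(4L, min(300L, p), by = 4L), seq(320L, p, by = 20L))
  sort(unique(c(g[g <= p], p)))
}

#' Incremental feature selection by cross-validated AUROC
#'
#' For every subset size n in `nGrid`, fits the classifier on the top-n
#' features of the ranking under k-fold cross-validation and records the
#' mean validation AUROC.  The optimal n maximizes the mean AUROC
#' (smallest n on ties).
#'
#' @param ranking A [FeatureRanking-class].
#' @param X A [FeatureMatrix-class] or numeric matrix.
#' @param y Binary labels.
#' @param nGrid Integer vector of subset sizes to evaluate.
#' @param cv A [cvConfig()] (fold seed shared with model tuning so curves
#'   are comparable).
#' @param algorithm Classifier used along the curve (default xgboost).
#' @param params Classifier hyperparameters.
#' @return A [SelectionResult-class].
#' @export
incrementalSelection <- function(ranking, X, y = NULL,
                                 nGrid = ifsGrid(ncol(X)),
                                 cv = cvConfig(),
                                 algorithm = "xgboost",
                                 params = list(max_depth = 6, eta = 0.1,
                                               nrounds = 150)) {
  d <- .resolveXy(X, y)
  if (!length(nGrid)) stop("nGrid must be non-empty")
  nGrid <- sort(unique(as.integer(nGrid)))
  if (any(nGrid < 1L) || any(nGrid > ncol(d$X)))
    stop("nGrid values must lie in [1, ncol(X)]")
  ord <- match(rankedFeatures(ranking), colnames(d$X))
  if (anyNA(ord))
    stop("ranking names do not match the feature columns")
  folds <- makeFolds(d$y, cv)
  auc <- vapply(nGrid, function(n) {
    .cvAUROC(d$X[, ord[seq_len(n)], drop = FALSE], d$y, folds,
             algorithm, params, seed = cv$seed)
  }, 0)
  best <- which(auc == max(auc))[1]
  new("SelectionResult",
      curve = data.frame(n = nGrid, auroc = auc),
      bestN = nGrid[best],
      bestAUROC = auc[best],
      selectedNames = rankedFeatures(ranking)[seq_len(nGrid[best])])
}

#' Write a SelectionResult as JSON
#'
#' @param x A [SelectionResult-class].
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
writeSelection <- function(x, path) {
  jsonlite::write_json(
    list(curve = x@curve, best_n = x@bestN, best_auroc = x@bestAUROC,
         selected = x@selectedNames),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
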