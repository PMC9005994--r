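# End-to-end workflows: the simulate -> encode -> rank -> select ->
# tune -> train -> evaluate pipeline, and FASTA batch prediction.

#' Default (reduced) xgboost tuning grid for desk-scale runs
#'
#' A 2 x 2 x 2 grid spanning the corners of the published search ranges,
#' sized for workstation runs; use [xgbReferenceGrid()] for the full
#' 280-combination search.
#'
#' @return A `modelSpec` for xgboost.
#' @export
xgbSmallGrid <- function() {
  modelSpec("xgboost", grid = list(
    max_depth = c(2L, 6L),
    learning_rate = c(0.02, 0.1),
    n_estimators = c(100L, 300L)))
}

#' Run the full m5C prediction pipeline on a synthetic benchmark
#'
#' Executes simulate -> encode -> rank -> incremental selection -> tune
#' -> final training -> evaluation, writing every intermediate artifact
#' under `outDir` and a final JSON report.  All stage seeds are derived
#' from the single `seed`.
#'
#' @param outDir Output directory for artifacts.
#' @param seed Top-level run seed.
#' @param nPos,nNeg,effect,biasedPositions Synthetic benchmark settings
#'   (see [simulateSegments()]).
#' @param rankMethod Ranking method: `"shap"`, `"fscore"` or `"mrmr"`.
#' @param shapParams Ranking-model hyperparameters for SHAP.
#' @param nGrid Subset sizes for incremental selection.
#' @param ifsParams Classifier hyperparameters along the IFS curve.
#' @param tuningGrid A [modelSpec()] for the hyperparameter search.
#' @param k Cross-validation folds.
#' @param verbose Log stage progress to stderr.
#' @return Invisibly, the report list (also written to
#'   `<outDir>/report.json`).
#' @export
runPipeline <- function(outDir, seed = 1L,
                        nPos = 500L, nNeg = 500L, effect = 0.5,
                        biasedPositions = defaultBiasedPositions(),
                        rankMethod = c("shap", "fscore", "mrmr"),
                        shapParams = list(max_depth = 6, eta = 0.1,
                                          nrounds = 300),
                        nGrid = c(8L, 16L, 24L, 32L, 48L, 64L, 96L,
                                  128L, 192L, 256L, 808L),
                        ifsParams = list(max_depth = 4, eta = 0.1,
                                         nrounds = 100),
                        tuningGrid = xgbSmallGrid(),
                        k = 5L, verbose = TRUE) {
  rankMethod <- match.arg(rankMethod)
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[", format(Sys.time(),
                                                        "%H:%M:%S"),
                                            "] ", ...)

  say("simulate: ", nPos, "+", nNeg, " segments, effect ", effect)
  segs <- simulateSegments(nPos, nNeg, effect = effect,
                           biasedPositions = biasedPositions,
                           seed = deriveSeed(seed, "simulate"))
  writeFixture(segs, file.path(outDir, "segments.fasta"),
               file.path(outDir, "labels.tsv"))

  say("embed: training CBOW k-mer embedding")
  emb <- trainEmbedding(segs, seed = deriveSeed(seed, "embedding"))

  say("encode: seven feature families")
  fm <- encodeSegments(segs, model = emb)
  writeFeatureCSV(fm, file.path(outDir, "features.csv"))
  X <- featureValues(fm)
  y <- segmentLabels(fm)

  say("rank: ", rankMethod)
  ranking <- switch(rankMethod,
    shap = rankByShap(X, y, params = shapParams,
                      seed = deriveSeed(seed, "ranking")),
    fscore = rankByFscore(X, y),
    mrmr = rankByMrmr(X, y, nSelect = min(300L, ncol(X))))
  writeRanking(ranking, file.path(outDir, "ranking.tsv"))

  cv <- cvConfig(k = k, seed = deriveSeed(seed, "folds"))
  nGrid <- nGrid[nGrid <= ncol(X)]
  say("select: incremental selection over ", length(nGrid),
      " subset sizes")
  sel <- incrementalSelection(ranking, X, y, nGrid = nGrid, cv = cv,
                              params = ifsParams)
  writeSelection(sel, file.path(outDir, "selection.json"))
  Xsel <- X[, selectedFeatures(sel), drop = FALSE]

  say("tune: ", nrow(expand.grid(tuningGrid$grid)), " combinations")
  tuned <- gridSearchCV(Xsel, y, tuningGrid, cv = cv)

  say("train: final ", tuningGrid$algorithm, " model")
  model <- trainModel(Xsel, y, algorithm = tuningGrid$algorithm,
                      params = tuned$bestParams,
                      seed = deriveSeed(seed, "model"),
                      embedding = emb)
  saveModel(model, file.path(outDir, "model"))

  say("evaluate: out-of-fold cross-validation metrics")
  folds <- makeFolds(y, cv)
  oof <- numeric(length(y))
  for (f in sort(unique(folds))) {
    tr <- folds != f
    fit <- .fitOne(tuningGrid$algorithm, Xsel[tr, , drop = FALSE],
                   y[tr], tuned$bestParams, seed = cv$seed)
    oof[!tr] <- .predictOne(tuningGrid$algorithm, fit,
                            Xsel[!tr, , drop = FALSE])
  }
  report_metrics <- evaluateScores(y, oof, threshold = 0.5)
  writeMetricsReport(report_metrics, file.path(outDir, "metrics.json"),
                     curves = TRUE)

  report <- list(
    seed = seed,
    n_pos = nPos, n_neg = nNeg, effect = effect,
    rank_method = rankMethod,
    n_features_total = ncol(X),
    best_n = bestN(sel),
    best_cv_auroc = bestAUROC(sel),
    tuned_params = tuned$bestParams,
    tuned_cv_auroc = tuned$bestAUROC,
    cv_metrics = as.list(metricValues(report_metrics)))
  jsonlite::write_json(report, file.path(outDir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: best n = ", bestN(sel), ", CV AUROC = ",
      round(bestAUROC(sel), 4))
  invisible(report)
}

#' Score every candidate cytosine of FASTA input sequences
#'
#' Reads sequences of arbitrary length (at least the window width),
#' extracts every cytosine with a full 41-nt context, encodes the
#' feature families required by the model's contract, scores each
#' candidate, and calls sites at the chosen operating point.
#'
#' @param input FASTA path, named character vector, or a
#'   [SegmentSet-class] of ready-made windows.
#' @param model A [SiteModel-class] (or a model artifact directory).
#' @param threshold Decision threshold; defaults to the model's.
#' @param targetFpr When given instead of `threshold`, the threshold is
#'   matched to this false-positive rate on the model's training
#'   calibration scores.
#' @param flank Window flank (default 20).
#' @return data.frame with columns id, position, score, call.
#' @export
predictFasta <- function(input, model, threshold = NULL,
                         targetFpr = NULL, flank = 20L) {
  if (is.character(model) && length(model) == 1L) model <- loadModel(model)
  stopifnot(is(model, "SiteModel"))
  segs <- if (is(input, "SegmentSet")) input
  else {
    seqs <- if (length(input) == 1L && file.exists(input))
      as.character(Biostrings::readBStringSet(input))
    else as.character(input)
    names(seqs) <- sub("\\s.*$", "", names(seqs))
    extractCandidates(seqs, flank = flank)
  }
  if (!length(segs))
    return(data.frame(id = character(), position = integer(),
                      score = numeric(), call = integer()))
  blocks <- unique(.blockFromName(modelFeatures(model)))
  fm <- encodeSegments(segs, model = model@embedding, blocks = blocks)
  scores <- predictScores(model, fm)
  if (!is.null(targetFpr)) {
    threshold <- thresholdForFpr(model@calibration$labels,
                                 model@calibration$scores,
                                 targetFpr)
  } else if (is.null(threshold)) {
    threshold <- decisionThreshold(model)
  }
  data.frame(id = names(segs),
             position = centerOffset(segs),
             score = scores,
             call = as.integer(scores >= threshold))
}
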