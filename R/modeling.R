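# Classifier training: stratified CV, grid search, final fits.

#' Cross-validation configuration
#'
#' @param k Number of folds (default 5).
#' @param seed Fold seed.
#' @param shuffle Shuffle before assignment (default TRUE).
#' @return A list with class `cvConfig`.
#' @export
cvConfig <- function(k = 5L, seed = 1L, shuffle = TRUE) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  structure(list(k = k, seed = as.integer(seed), shuffle = shuffle),
            class = "cvConfig")
}

#' Stratified fold assignment
#'
#' Samples are assigned to folds class by class in one global
#' round-robin, so fold sizes differ by at most 1 overall and each
#' fold's class ratio is within one sample of the global ratio.
#' Deterministic given the seed.
#'
#' @param y Binary 0/1 labels.
#' @param cv A [cvConfig()].
#' @return Integer vector of fold ids in 1..k.
#' @export
makeFolds <- function(y, cv = cvConfig()) {
  y <- .assertBinaryLabels(y)
  n <- length(y)
  if (cv$k > n) stop("k must not exceed the number of samples")
  set.seed(cv$seed)
  ord <- unlist(lapply(c(1L, 0L), function(cl) {
    idx <- which(y == cl)
    if (cv$shuffle) sample(idx) else idx
  }), use.names = FALSE)
  folds <- integer(n)
  folds[ord] <- rep_len(seq_len(cv$k), n)
  folds
}

#' Model specification for tuning
#'
#' @param algorithm One of `"xgboost"`, `"rf"`, `"svm"`.
#' @param grid Named list of hyperparameter candidate vectors (python-style
#'   names accepted for xgboost: `learning_rate`, `n_estimators`,
#'   `max_depth`).
#' @param fixed Named list of fixed parameters merged into every
#'   combination.
#' @return A list with class `modelSpec`.
#' @export
modelSpec <- function(algorithm = c("xgboost", "rf", "svm"),
                      grid = list(), fixed = list()) {
  algorithm <- match.arg(algorithm)
  if (!length(grid)) stop("grid must be non-empty for tuned runs")
  structure(list(algorithm = algorithm, grid = grid, fixed = fixed),
            class = "modelSpec")
}

#' The published XGBoost tuning grid
#'
#' max_depth in (2, 4, 6, 8, 10, 12, 14, 16), learning_rate in (0.005,
#' 0.01, 0.02, 0.05, 0.1), n_estimators in (1600, 1800, 2000, 2200,
#' 2400, 2600, 2800): 280 combinations.
#'
#' @return A `modelSpec` for xgboost.
#' @export
xgbReferenceGrid <- function() {
  modelSpec("xgboost", grid = list(
    max_depth = c(2L, 4L, 6L, 8L, 10L, 12L, 14L, 16L),
    learning_rate = c(0.005, 0.01, 0.02, 0.05, 0.1),
    n_estimators = seq(1600L, 2800L, by = 200L)))
}

# --- internal fit/predict per algorithm -------------------------------

.xgbParams <- function(params) {
  p <- params
  if (!is.null(p$learning_rate)) { p$eta <- p$learning_rate
                                   p$learning_rate <- NULL }
  if (!is.null(p$n_estimators)) { p$nrounds <- p$n_estimators
                                  p$n_estimators <- NULL }
  if (is.null(p$nrounds)) p$nrounds <- 100L
  p
}

.fitXGB <- function(X, y, params, seed = 1L) {
  p <- .xgbParams(params)
  nrounds <- p$nrounds
  p$nrounds <- NULL
  xgboost::xgb.train(
    params = c(list(objective = "binary:logistic", nthread = 1,
                    seed = as.integer(seed)), p),
    data = xgboost::xgb.DMatrix(X, label = y, nthread = 1),
    nrounds = nrounds, verbose = 0)
}

.fitOne <- function(algorithm, X, y, params, seed = 1L) {
  switch(algorithm,
    xgboost = .fitXGB(X, y, params, seed),
    rf = {
      p <- params
      df <- data.frame(.y = factor(y, levels = c(0L, 1L)), X,
                       check.names = FALSE)
      ranger::ranger(
        dependent.variable.name = ".y", data = df,
        num.trees = if (is.null(p$num.trees)) 500L else p$num.trees,
        max.depth = if (is.null(p$max.depth)) 0L else p$max.depth,
        mtry = p$mtry, probability = TRUE,
        seed = as.integer(seed), num.threads = 1L)
    },
    svm = {
      set.seed(as.integer(seed))
      e1071::svm(
        x = X, y = factor(y, levels = c(0L, 1L)),
        kernel = "radial",
        cost = if (is.null(params$cost)) 1 else params$cost,
        gamma = if (is.null(params$gamma)) 1 / ncol(X) else params$gamma,
        probability = TRUE, scale = FALSE)
    },
    stop("unknown algorithm: ", algorithm))
}

.predictOne <- function(algorithm, fit, X) {
  switch(algorithm,
    xgboost = as.numeric(predict(fit, xgboost::xgb.DMatrix(X,
                                                           nthread = 1))),
    rf = as.numeric(predict(fit, data.frame(X, check.names = FALSE),
                            num.threads = 1L)$predictions[, "1"]),
    svm = {
      pr <- predict(fit, X, probability = TRUE)
      as.numeric(attr(pr, "probabilities")[, "1"])
    })
}

# mean per-fold validation AUROC of one configuration
.cvAUROC <- function(X, y, folds, algorithm, params, seed = 1L) {
  aucs <- vapply(sort(unique(folds)), function(f) {
    tr <- folds != f
    fit <- .fitOne(algorithm, X[tr, , drop = FALSE], y[tr], params, seed)
    sc <- .predictOne(algorithm, fit, X[!tr, , drop = FALSE])
    rocCurve(y[!tr], sc)$auc
  }, 0)
  mean(aucs)
}

#' Exhaustive grid search under cross-validation
#'
#' Every combination in the grid is evaluated by mean validation AUROC
#' over the same stratified folds; the best combination is the argmax,
#' with ties broken by grid order.
#'
#' @param X A [FeatureMatrix-class] or numeric matrix.
#' @param y Binary labels.
#' @param spec A [modelSpec()].
#' @param cv A [cvConfig()].
#' @return List with `bestParams`, `bestAUROC`, and `results` (one row
#'   per combination with its mean CV AUROC).
#' @export
gridSearchCV <- function(X, y = NULL, spec, cv = cvConfig()) {
  d <- .resolveXy(X, y)
  combos <- expand.grid(spec$grid, KEEP.OUT.ATTRS = FALSE)
  folds <- makeFolds(d$y, cv)
  auc <- vapply(seq_len(nrow(combos)), function(i) {
    params <- c(as.list(combos[i, , drop = FALSE]), spec$fixed)
    .cvAUROC(d$X, d$y, folds, spec$algorithm, params, seed = cv$seed)
  }, 0)
  best <- which(auc == max(auc))[1]
  list(bestParams = c(as.list(combos[best, , drop = FALSE]), spec$fixed),
       bestAUROC = auc[best],
       results = cbind(combos, auroc = auc))
}

#' Train a final site classifier on all rows
#'
#' @param X A [FeatureMatrix-class] or numeric matrix.
#' @param y Binary labels.
#' @param algorithm One of `"xgboost"`, `"rf"`, `"svm"`.
#' @param params Hyperparameters for the fit.
#' @param seed Fit seed.
#' @param threshold Default decision threshold (0.5).
#' @param embedding Optional [Word2VecModel-class] stored with the model
#'   so new sequences can be encoded at prediction time.
#' @return A [SiteModel-class].
#' @export
trainModel <- function(X, y = NULL, algorithm = "xgboost",
                       params = list(max_depth = 6, eta = 0.1,
                                     nrounds = 200),
                       seed = 1L, threshold = 0.5, embedding = NULL) {
  d <- .resolveXy(X, y)
  fit <- .fitOne(algorithm, d$X, d$y, params, seed)
  scores <- .predictOne(algorithm, fit, d$X)
  new("SiteModel", algorithm = algorithm, fit = fit,
      featureNames = colnames(d$X), threshold = threshold,
      params = params, seed = as.integer(seed),
      calibration = list(scores = scores, labels = d$y),
      embedding = embedding)
}

#' @describeIn SiteModel-class Algorithm of the fitted model.
#' @export
setMethod("modelAlgorithm", "SiteModel", function(x) x@algorithm)

#' @describeIn SiteModel-class The exact feature-column contract.
#' @export
setMethod("modelFeatures", "SiteModel", function(x) x@featureNames)

#' @describeIn SiteModel-class Decision threshold.
#' @export
setMethod("decisionThreshold", "SiteModel", function(x) x@threshold)

#' @describeIn SiteModel-class Replace the decision threshold.
#' @param value New threshold in [0, 1].
#' @export
setReplaceMethod("decisionThreshold", "SiteModel", function(x, value) {
  x@threshold <- as.numeric(value)
  validObject(x)
  x
})

#' @describeIn SiteModel-class Display a summary.
#' @export
setMethod("show", "SiteModel", function(object) {
  cat("SiteModel (", object@algorithm, "): ",
      length(object@featureNames), " features, threshold ",
      object@threshold, "\n", sep = "")
})

#' Predict m5C scores for encoded segments
#'
#' Refuses inputs whose feature columns do not match the model's
#' contract; columns may be supplied in any order and are aligned
#' internally.
#'
#' @param model A [SiteModel-class].
#' @param X A [FeatureMatrix-class] or numeric matrix with exactly the
#'   model's feature columns.
#' @return Numeric scores in [0, 1], one per row, in input order.
#' @export
predictScores <- function(model, X) {
  if (is(X, "FeatureMatrix")) X <- featureValues(X)
  X <- as.matrix(X)
  want <- model@featureNames
  have <- colnames(X)
  missing_ <- setdiff(want, have)
  if (length(missing_))
    stop("input is missing model feature columns: ",
         paste(utils::head(missing_, 5), collapse = ", "),
         if (length(missing_) > 5) " ...")
  X <- X[, want, drop = FALSE]
  .predictOne(model@algorithm, model@fit, X)
}

#' Save / load a model artifact directory
#'
#' The artifact holds the serialized estimator, the feature contract,
#' threshold, configuration, calibration scores and (when present) the
#' embedding model.
#'
#' @param model A [SiteModel-class].
#' @param dir Artifact directory (created if needed).
#' @return `dir` invisibly / a [SiteModel-class].
#' @export
saveModel <- function(model, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (model@algorithm == "xgboost") {
    xgboost::xgb.save(model@fit, file.path(dir, "estimator.ubj"))
  } else {
    saveRDS(model@fit, file.path(dir, "estimator.rds"))
  }
  jsonlite::write_json(
    list(algorithm = model@algorithm, feature_names = model@featureNames,
         threshold = model@threshold, params = model@params,
         seed = model@seed),
    file.path(dir, "config.json"), auto_unbox = TRUE, digits = NA)
  utils::write.table(
    data.frame(score = model@calibration$scores,
               label = model@calibration$labels),
    file.path(dir, "calibration.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  if (!is.null(model@embedding))
    writeEmbedding(model@embedding, file.path(dir, "embedding"))
  invisible(dir)
}

#' @rdname saveModel
#' @export
loadModel <- function(dir) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  fit <- if (cfg$algorithm == "xgboost")
    xgboost::xgb.load(file.path(dir, "estimator.ubj"))
  else readRDS(file.path(dir, "estimator.rds"))
  cal <- utils::read.delim(file.path(dir, "calibration.tsv"))
  emb <- if (dir.exists(file.path(dir, "embedding")))
    readEmbedding(file.path(dir, "embedding")) else NULL
  new("SiteModel", algorithm = cfg$algorithm, fit = fit,
      featureNames = cfg$feature_names, threshold = cfg$threshold,
      params = as.list(cfg$params), seed = as.integer(cfg$seed),
      calibration = list(scores = cal$score, labels = cal$label),
      embedding = emb)
}
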