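#' @import methods
#' @importFrom S4Vectors metadata metadata<- DataFrame
#' @importClassesFrom S4Vectors Annotated
#' @importClassesFrom Biostrings RNAStringSet
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom Biostrings RNAStringSet width subseq
NULL

.NT <- c("A", "C", "G", "U")

#' SegmentSet: fixed-width RNA windows centered on candidate cytosines
#'
#' A `SegmentSet` holds equal-width RNA segments of odd length 2*flank+1
#' (41 nt for the default flank of 20), each centered on a cytosine that is
#' a candidate m5C site.  Segments may carry binary labels (1 = methylated,
#' 0 = unmethylated) and record the 1-based position of the center cytosine
#' within the source sequence they were extracted from.
#'
#' @slot sequences An [Biostrings::RNAStringSet] of equal, odd widths whose
#'   center letter is always `C`; names are the unique segment identifiers.
#' @slot centerOffset Integer vector, 1-based position of the center C in
#'   the originating sequence (`NA` when unknown).
#' @slot label Integer vector of 0/1 labels (`NA` when unlabeled).
#' @slot speciesTag Optional single character tag for the set.
#'
#' @exportClass SegmentSet
setClass("SegmentSet",
  contains = "Annotated",
  representation(
    sequences = "RNAStringSet",
    centerOffset = "integer",
    label = "integer",
    speciesTag = "character"
  )
)

setValidity("SegmentSet", function(object) {
  msg <- character()
  n <- length(object@sequences)
  ids <- names(object@sequences)
  if (n > 0 && (is.null(ids) || anyNA(ids) || any(ids == "")))
    msg <- c(msg, "all segments must be named")
  if (n > 0 && anyDuplicated(ids))
    msg <- c(msg, "segment ids must be unique")
  if (length(object@centerOffset) != n)
    msg <- c(msg, "centerOffset length must match number of segments")
  if (length(object@label) != n)
    msg <- c(msg, "label length must match number of segments")
  if (!all(object@label %in% c(0L, 1L, NA_integer_)))
    msg <- c(msg, "labels must be 0, 1 or NA")
  if (length(object@speciesTag) > 1)
    msg <- c(msg, "speciesTag must be a single string")
  if (n > 0) {
    w <- Biostrings::width(object@sequences)
    if (length(unique(w)) != 1L)
      msg <- c(msg, "all segments must have equal width")
    else {
      L <- w[1]
      if (L %% 2L == 0L)
        msg <- c(msg, "segment width must be odd (2*flank+1)")
      else {
        ctr <- as.character(Biostrings::subseq(object@sequences,
                                               (L + 1L) %/% 2L, (L + 1L) %/% 2L))
        if (!all(ctr == "C"))
          msg <- c(msg, "center nucleotide must be C in every segment")
      }
      chars <- unique(strsplit(paste(as.character(object@sequences),
                                     collapse = ""), "")[[1]])
      if (!all(chars %in% .NT))
        msg <- c(msg, "segments must contain only A, C, G, U")
    }
  }
  if (length(msg)) msg else TRUE
})

#' FeatureMatrix: encoded features for a set of segments
#'
#' Extends [SummarizedExperiment::SummarizedExperiment] with features as
#' rows and segments as columns.  `rowData` carries the feature-family
#' block of every feature; `colData` carries segment labels.  Use
#' [featureValues()] to obtain the segments-by-features numeric matrix in
#' the orientation expected by classifiers.
#'
#' @exportClass FeatureMatrix
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!"features" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'features' is required")
  if (!"block" %in% colnames(SummarizedExperiment::rowData(object)))
    msg <- c(msg, "rowData must contain a 'block' column")
  rn <- rownames(object)
  if (is.null(rn) || anyDuplicated(rn))
    msg <- c(msg, "feature names must be present and unique")
  if (length(msg)) msg else TRUE
})

#' FeatureRanking: an ordered ranking of feature columns
#'
#' @slot method One of `"shap"`, `"fscore"`, `"mrmr"`.
#' @slot orderedNames Feature names, best first; a permutation of the
#'   ranked matrix's columns.
#' @slot scores Numeric score per name (mean |SHAP|, F-score, or the mRMR
#'   selection-step criterion; `NA` for features beyond the mRMR selection
#'   horizon).
#' @slot provenance List recording configuration and seed.
#'
#' @exportClass FeatureRanking
setClass("FeatureRanking",
  representation(
    method = "character",
    orderedNames = "character",
    scores = "numeric",
    provenance = "list"
  )
)

setValidity("FeatureRanking", function(object) {
  msg <- character()
  if (!object@method %in% c("shap", "fscore", "mrmr"))
    msg <- c(msg, "method must be one of shap, fscore, mrmr")
  if (anyDuplicated(object@orderedNames))
    msg <- c(msg, "orderedNames must be unique")
  if (length(object@scores) != length(object@orderedNames))
    msg <- c(msg, "scores and orderedNames must have equal length")
  if (object@method %in% c("shap", "fscore") && length(object@scores) > 1) {
    s <- object@scores
    if (anyNA(s) || is.unsorted(rev(s)))
      msg <- c(msg, "shap/fscore scores must be non-increasing and non-NA")
  }
  if (length(msg)) msg else TRUE
})

#' SelectionResult: outcome of incremental feature selection
#'
#' @slot curve data.frame with columns `n` and `auroc` (mean CV AUROC of a
#'   classifier fitted on the top-n features).
#' @slot bestN Subset size maximizing mean CV AUROC (smallest on ties).
#' @slot bestAUROC The maximal mean CV AUROC.
#' @slot selectedNames The first `bestN` names of the ranking.
#'
#' @exportClass SelectionResult
setClass("SelectionResult",
  representation(
    curve = "data.frame",
    bestN = "integer",
    bestAUROC = "numeric",
    selectedNames = "character"
  )
)

setValidity("SelectionResult", function(object) {
  msg <- character()
  if (!all(c("n", "auroc") %in% colnames(object@curve)))
    msg <- c(msg, "curve must have columns n and auroc")
  if (nrow(object@curve)) {
    if (abs(object@bestAUROC - max(object@curve$auroc)) > 1e-12)
      msg <- c(msg, "bestAUROC must equal the curve maximum")
    if (length(object@selectedNames) != object@bestN)
      msg <- c(msg, "selectedNames must have length bestN")
  }
  if (length(msg)) msg else TRUE
})

#' Word2VecModel: k-mer embedding trained by CBOW
#'
#' Token-to-vector map learned with a continuous-bag-of-words objective
#' over overlapping k-mers of the training segments.
#'
#' @slot vectors Numeric matrix, one row per vocabulary token.
#' @slot k k-mer size of the tokenizer.
#' @slot window Context half-window (tokens each side).
#' @slot epochs Training epochs.
#' @slot seed Seed used for initialization.
#'
#' @exportClass Word2VecModel
setClass("Word2VecModel",
  representation(
    vectors = "matrix",
    k = "integer",
    window = "integer",
    epochs = "integer",
    seed = "integer"
  )
)

setValidity("Word2VecModel", function(object) {
  if (is.null(rownames(object@vectors)))
    return("embedding vectors must have token rownames")
  TRUE
})

#' SiteModel: a fitted m5C site classifier
#'
#' Couples a fitted estimator with its feature-column contract, decision
#' threshold, training calibration scores (used for FPR-matched
#' thresholds) and, when the features include the embedding block, the
#' embedding model needed to encode new sequences.
#'
#' @slot algorithm One of `"xgboost"`, `"rf"`, `"svm"`.
#' @slot fit The fitted estimator object.
#' @slot featureNames Exact ordered feature-column contract.
#' @slot threshold Default decision threshold (score >= threshold is a
#'   positive call).
#' @slot params Hyperparameters used for the final fit.
#' @slot seed Seed of the fit.
#' @slot calibration List with `scores` and `labels` on the training set.
#' @slot embedding A [Word2VecModel] or `NULL`.
#'
#' @exportClass SiteModel
setClass("SiteModel",
  representation(
    algorithm = "character",
    fit = "ANY",
    featureNames = "character",
    threshold = "numeric",
    params = "list",
    seed = "integer",
    calibration = "list",
    embedding = "ANY"
  )
)

setValidity("SiteModel", function(object) {
  msg <- character()
  if (!object@algorithm %in% c("xgboost", "rf", "svm"))
    msg <- c(msg, "algorithm must be one of xgboost, rf, svm")
  if (length(object@threshold) != 1 || object@threshold < 0 ||
      object@threshold > 1)
    msg <- c(msg, "threshold must be a single value in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' MetricsReport: classification performance summary
#'
#' Confusion counts at a decision threshold, the seven scalar metrics
#' (Sen, Spe, Pre, Acc, F1, MCC, FOR), and full ROC / precision-recall
#' curves with their areas.
#'
#' @slot counts Named integer vector TP, FP, TN, FN.
#' @slot metrics Named numeric vector Sen, Spe, Pre, Acc, F1, MCC, FOR.
#' @slot auroc Area under the ROC curve.
#' @slot auprc Area under the precision-recall curve (step-wise).
#' @slot rocPoints data.frame with columns fpr, tpr.
#' @slot prcPoints data.frame with columns recall, precision.
#' @slot threshold Decision threshold used for the counts.
#'
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(
    counts = "integer",
    metrics = "numeric",
    auroc = "numeric",
    auprc = "numeric",
    rocPoints = "data.frame",
    prcPoints = "data.frame",
    threshold = "numeric"
  )
)

setValidity("MetricsReport", function(object) {
  msg <- character()
  if (!identical(sort(names(object@counts)), sort(c("TP", "FP", "TN", "FN"))))
    msg <- c(msg, "counts must be named TP, FP, TN, FN")
  if (any(object@counts < 0))
    msg <- c(msg, "counts must be non-negative")
  m <- object@metrics
  if (!all(c("Sen", "Spe", "Pre", "Acc", "F1", "MCC", "FOR") %in% names(m)))
    msg <- c(msg, "metrics must include Sen, Spe, Pre, Acc, F1, MCC, FOR")
  if (length(msg)) msg else TRUE
})
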