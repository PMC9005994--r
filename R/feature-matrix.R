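#' Construct a FeatureMatrix
#'
#' @param values Numeric matrix, segments in rows, features in columns
#'   (column names are the feature names, row names the segment ids).
#' @param blocks Character vector assigning each feature column to a
#'   feature-family block.
#' @param label Optional 0/1 labels per segment.
#' @return A [FeatureMatrix-class] (features x segments internally,
#'   following the SummarizedExperiment convention).
#' @export
FeatureMatrix <- function(values, blocks, label = NULL) {
  values <- as.matrix(values)
  if (is.null(colnames(values))) stop("feature columns must be named")
  if (length(blocks) != ncol(values))
    stop("one block per feature column is required")
  if (is.null(label)) label <- rep(NA_integer_, nrow(values))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(features = t(values)),
    rowData = S4Vectors::DataFrame(block = as.character(blocks),
                                   row.names = colnames(values)),
    colData = S4Vectors::DataFrame(label = as.integer(label),
                                   row.names = rownames(values)))
  new("FeatureMatrix", se)
}

#' @describeIn FeatureMatrix Segments-by-features numeric matrix (the
#'   orientation classifiers consume).
#' @param x,object A `FeatureMatrix`.
#' @export
setMethod("featureValues", "FeatureMatrix", function(x)
  t(SummarizedExperiment::assay(x, "features")))

#' @describeIn FeatureMatrix Feature-family block of every feature.
#' @export
setMethod("featureBlocks", "FeatureMatrix", function(x)
  stats::setNames(SummarizedExperiment::rowData(x)$block, rownames(x)))

#' @describeIn FeatureMatrix Named list mapping each block to its feature
#'   column indices (in canonical order).
#' @export
setMethod("blockMap", "FeatureMatrix", function(x) {
  b <- SummarizedExperiment::rowData(x)$block
  split(seq_along(b), factor(b, levels = unique(b)))
})

#' @describeIn FeatureMatrix Segment labels.
#' @export
setMethod("segmentLabels", "FeatureMatrix", function(x)
  SummarizedExperiment::colData(x)$label)

#' @describeIn FeatureMatrix Replace segment labels.
#' @param value Replacement labels.
#' @export
setReplaceMethod("segmentLabels", "FeatureMatrix", function(x, value) {
  SummarizedExperiment::colData(x)$label <-
    rep_len(as.integer(value), ncol(x))
  x
})

#' @describeIn FeatureMatrix Display a summary.
#' @export
setMethod("show", "FeatureMatrix", function(object) {
  bm <- blockMap(object)
  cat("FeatureMatrix:", ncol(object), "segments x", nrow(object),
      "features\n")
  cat("  blocks:",
      paste(sprintf("%s(%d)", names(bm), lengths(bm)), collapse = " "),
      "\n")
  nlab <- sum(!is.na(segmentLabels(object)))
  if (nlab) cat("  labeled segments:", nlab, "\n")
})

#' Write a FeatureMatrix to CSV
#'
#' Columns: `id`, optional `label`, then the canonical feature names.
#'
#' @param x A [FeatureMatrix-class].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
writeFeatureCSV <- function(x, path) {
  df <- data.frame(id = colnames(x), label = segmentLabels(x),
                   featureValues(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a FeatureMatrix from CSV written by [writeFeatureCSV()]
#'
#' Block membership is recovered from the canonical feature-name
#' prefixes.
#'
#' @param path CSV path.
#' @return A [FeatureMatrix-class].
#' @export
readFeatureCSV <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  lab <- if ("label" %in% colnames(df)) df$label else NULL
  feat <- as.matrix(df[, setdiff(colnames(df), c("id", "label")),
                       drop = FALSE])
  rownames(feat) <- df$id
  FeatureMatrix(feat, blocks = .blockFromName(colnames(feat)), label = lab)
}

.blockFromName <- function(nm) {
  sub("_.*$", "", nm)
}
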