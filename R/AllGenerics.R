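#' @rdname SegmentSet
#' @export
setGeneric("segmentLabels", function(x) standardGeneric("segmentLabels"))

#' @rdname SegmentSet
#' @export
setGeneric("segmentLabels<-",
           function(x, value) standardGeneric("segmentLabels<-"))

#' @rdname SegmentSet
#' @export
setGeneric("centerOffset", function(x) standardGeneric("centerOffset"))

#' @rdname SegmentSet
#' @export
setGeneric("speciesTag", function(x) standardGeneric("speciesTag"))

#' @rdname FeatureMatrix
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname FeatureMatrix
#' @export
setGeneric("featureBlocks", function(x) standardGeneric("featureBlocks"))

#' @rdname FeatureMatrix
#' @export
setGeneric("blockMap", function(x) standardGeneric("blockMap"))

#' @rdname FeatureRanking-class
#' @export
setGeneric("rankedFeatures", function(x) standardGeneric("rankedFeatures"))

#' @rdname FeatureRanking-class
#' @export
setGeneric("rankingScores", function(x) standardGeneric("rankingScores"))

#' @rdname FeatureRanking-class
#' @export
setGeneric("rankingMethod", function(x) standardGeneric("rankingMethod"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectionCurve", function(x) standardGeneric("selectionCurve"))

#' @rdname SelectionResult-class
#' @export
setGeneric("bestN", function(x) standardGeneric("bestN"))

#' @rdname SelectionResult-class
#' @export
setGeneric("bestAUROC", function(x) standardGeneric("bestAUROC"))

#' @rdname SelectionResult-class
#' @export
setGeneric("selectedFeatures", function(x) standardGeneric("selectedFeatures"))

#' @rdname SiteModel-class
#' @export
setGeneric("modelAlgorithm", function(x) standardGeneric("modelAlgorithm"))

#' @rdname SiteModel-class
#' @export
setGeneric("modelFeatures", function(x) standardGeneric("modelFeatures"))

#' @rdname SiteModel-class
#' @export
setGeneric("decisionThreshold", function(x) standardGeneric("decisionThreshold"))

#' @rdname SiteModel-class
#' @export
setGeneric("decisionThreshold<-",
           function(x, value) standardGeneric("decisionThreshold<-"))

#' @rdname MetricsReport-class
#' @export
setGeneric("metricValues", function(x) standardGeneric("metricValues"))

#' @rdname MetricsReport-class
#' @export
setGeneric("confusionValues", function(x) standardGeneric("confusionValues"))

#' @rdname Word2VecModel-class
#' @export
setGeneric("tokenVectors", function(x) standardGeneric("tokenVectors"))
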