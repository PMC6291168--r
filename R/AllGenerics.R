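#' @rdname GenomeAnnotation
#' @export
setGeneric("genes", function(x) standardGeneric("genes"))

#' @rdname GenomeAnnotation
#' @export
setGeneric("chromSizes", function(x) standardGeneric("chromSizes"))

#' @rdname GenomeAnnotation
#' @export
setGeneric("tssSites", function(x) standardGeneric("tssSites"))

#' @rdname GenomeAnnotation
#' @export
setGeneric("tesSites", function(x) standardGeneric("tesSites"))

#' @rdname PeakSet
#' @export
setGeneric("peaks", function(x) standardGeneric("peaks"))

#' @rdname PeakSet
#' @export
setGeneric("peakTarget", function(x) standardGeneric("peakTarget"))

#' @rdname PeakSet
#' @export
setGeneric("peakCondition", function(x) standardGeneric("peakCondition"))

#' @rdname BinnedTrackSet
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname BinnedTrackSet
#' @export
setGeneric("marks", function(x) standardGeneric("marks"))

#' @rdname BinnedTrackSet
#' @export
setGeneric("trackCounts", function(x) standardGeneric("trackCounts"))

#' @rdname BinnedTrackSet
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname StateModel
#' @export
setGeneric("nStates", function(x) standardGeneric("nStates"))

#' @rdname StateModel
#' @export
setGeneric("startProb", function(x) standardGeneric("startProb"))

#' @rdname StateModel
#' @export
setGeneric("transMat", function(x) standardGeneric("transMat"))

#' @rdname StateModel
#' @export
setGeneric("emissionProb", function(x) standardGeneric("emissionProb"))

#' @rdname StatePath-class
#' @export
setGeneric("statePath", function(x) standardGeneric("statePath"))

#' @rdname ClusterAssignment-class
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @rdname PatternAssignment-class
#' @export
setGeneric("patternLabels", function(x) standardGeneric("patternLabels"))
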