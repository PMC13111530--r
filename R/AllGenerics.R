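#' @importFrom rlang %||%
NULL

#' @rdname SpikeRecording-class
#' @param x,object a \linkS4class{SpikeRecording} (or, where documented, a
#'   \linkS4class{Correlogram} / \linkS4class{CorrelogramSet}).
#' @export
setGeneric("unitIds", function(x) standardGeneric("unitIds"))

#' @rdname SpikeRecording-class
#' @param unit a unit id; if missing, all trains are returned as a list.
#' @export
setGeneric("spikeTimes", function(x, unit) standardGeneric("spikeTimes"))

#' @rdname SpikeRecording-class
#' @export
setGeneric("nUnits", function(x) standardGeneric("nUnits"))

#' @rdname SpikeRecording-class
#' @export
setGeneric("recordingDuration", function(x) standardGeneric("recordingDuration"))

#' @rdname SpikeRecording-class
#' @export
setGeneric("treatments", function(x) standardGeneric("treatments"))

#' @rdname CorrelogramSpec-class
#' @param x a \linkS4class{CorrelogramSpec} or \linkS4class{Correlogram}.
#' @export
setGeneric("binWidth", function(x) standardGeneric("binWidth"))

#' @rdname CorrelogramSpec-class
#' @export
setGeneric("lagRange", function(x) standardGeneric("lagRange"))

#' @rdname CorrelogramSpec-class
#' @export
setGeneric("nBins", function(x) standardGeneric("nBins"))

#' @rdname Correlogram-class
#' @param x a \linkS4class{Correlogram}.
#' @export
setGeneric("binCenters", function(x) standardGeneric("binCenters"))

#' @rdname Correlogram-class
#' @export
setGeneric("probs", function(x) standardGeneric("probs"))

#' @rdname Correlogram-class
#' @export
setGeneric("totalEvents", function(x) standardGeneric("totalEvents"))

#' @rdname Correlogram-class
#' @export
setGeneric("nPairs", function(x) standardGeneric("nPairs"))

#' Sparsity flag of a correlogram
#'
#' A correlogram is sparse when it rests on too few raster events for its
#' shape to be meaningful: when the product of reference and comparison event
#' counts is at or below \code{threshold}, or when it holds no events at all.
#' Sparse correlograms are excluded from metric analysis but retained
#' (flagged) in outputs. The default threshold 0 keeps every correlogram
#' that contains at least one event.
#'
#' @param x a \linkS4class{Correlogram} or \linkS4class{CorrelogramSet}.
#' @param threshold non-negative count; pairs with
#'   \code{nRef * nCmp <= threshold} are sparse.
#' @return logical scalar (Correlogram) or vector over pairs
#'   (CorrelogramSet).
#' @examples
#' cg <- buildCorrelogram(c(0, 0.5), c(0.1, 0.6), correlogramSpec(0.2, 0.01),
#'                        refId = "a", cmpId = "b")
#' isSparse(cg)            # FALSE: 2 events landed in range
#' isSparse(cg, threshold = 10)  # TRUE: 2*2 = 4 <= 10
#' @export
setGeneric("isSparse", function(x, threshold = 0) standardGeneric("isSparse"))
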