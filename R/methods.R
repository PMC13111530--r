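# Accessors and show methods for the core classes.

#' @rdname SpikeRecording-class
#' @export
setMethod("unitIds", "SpikeRecording", function(x) names(x@trains))

#' @rdname SpikeRecording-class
#' @export
setMethod("spikeTimes", "SpikeRecording", function(x, unit) {
  if (missing(unit)) return(x@trains)
  if (!unit %in% names(x@trains))
    stop("unknown unit id: ", unit)
  x@trains[[unit]]
})

#' @rdname SpikeRecording-class
#' @export
setMethod("nUnits", "SpikeRecording", function(x) length(x@trains))

#' @rdname SpikeRecording-class
#' @export
setMethod("recordingDuration", "SpikeRecording", function(x) x@duration)

#' @rdname SpikeRecording-class
#' @export
setMethod("treatments", "SpikeRecording", function(x) x@treatments)

setMethod("show", "SpikeRecording", function(object) {
  n <- nUnits(object)
  tot <- sum(lengths(object@trains))
  cat("SpikeRecording with", n, "unit(s),", tot, "events,",
      sprintf("duration %.6g s\n", object@duration))
  if (nrow(object@treatments)) {
    cat("treatments:",
        paste(sprintf("%s@%.6gs", object@treatments$label,
                      object@treatments$time), collapse = ", "), "\n")
  }
  if (nzchar(object@source)) cat("source:", object@source, "\n")
})

#' @rdname CorrelogramSpec-class
#' @export
setMethod("binWidth", "CorrelogramSpec", function(x) x@binWidth)

#' @rdname CorrelogramSpec-class
#' @export
setMethod("lagRange", "CorrelogramSpec", function(x) x@range)

#' @rdname CorrelogramSpec-class
#' @export
setMethod("nBins", "CorrelogramSpec", function(x) {
  2L * as.integer(round(x@range / x@binWidth)) + 1L
})

setMethod("show", "CorrelogramSpec", function(object) {
  cat(sprintf("CorrelogramSpec: lags +/- %.6g s, bin width %.6g s (%d bins)\n",
              object@range, object@binWidth, nBins(object)))
  if (length(object@referenceSubset))
    cat("reference subset:", paste(object@referenceSubset, collapse = ", "), "\n")
})

#' @rdname Correlogram-class
#' @export
setMethod("binCenters", "Correlogram", function(x) x@binCenters)

#' @rdname Correlogram-class
#' @param object a \linkS4class{Correlogram}.
#' @param ... ignored.
#' @export
setMethod("counts", "Correlogram", function(object, ...) object@counts)

#' @rdname Correlogram-class
#' @export
setMethod("probs", "Correlogram", function(x) {
  tot <- sum(x@counts)
  if (tot == 0L) return(rep(NA_real_, length(x@counts)))
  x@counts / tot
})

#' @rdname Correlogram-class
#' @export
setMethod("totalEvents", "Correlogram", function(x) sum(x@counts))

#' @rdname Correlogram-class
#' @export
setMethod("nPairs", "Correlogram", function(x) {
  as.numeric(x@nRef) * as.numeric(x@nCmp)
})

#' @rdname Correlogram-class
#' @export
setMethod("binWidth", "Correlogram", function(x) x@binWidth)

#' @rdname Correlogram-class
#' @export
setMethod("lagRange", "Correlogram", function(x) x@range)

#' @rdname Correlogram-class
#' @export
setMethod("nBins", "Correlogram", function(x) length(x@counts))

#' @rdname isSparse
#' @export
setMethod("isSparse", "Correlogram", function(x, threshold = 0) {
  nPairs(x) <= threshold || sum(x@counts) == 0L
})

setMethod("show", "Correlogram", function(object) {
  cat(sprintf("Correlogram %s (cmp) vs %s (ref), region %d\n",
              object@cmpId, object@refId, object@regionIndex))
  cat(sprintf("  %d bins of %.6g s over +/- %.6g s; S = %d events (%d x %d raster events)\n",
              length(object@counts), object@binWidth, object@range,
              sum(object@counts), object@nRef, object@nCmp))
})

#' @rdname isSparse
#' @export
setMethod("isSparse", "CorrelogramSet", function(x, threshold = 0) {
  cd <- colData(x)
  as.numeric(cd$nRef) * as.numeric(cd$nCmp) <= threshold | cd$total == 0L
})

setMethod("show", "CorrelogramSet", function(object) {
  cd <- colData(object)
  cat(sprintf("CorrelogramSet: %d correlograms x %d bins (region %s)\n",
              ncol(object), nrow(object),
              paste(unique(cd$regionIndex), collapse = ",")))
  cat(sprintf("  %d empty, %d total events\n",
              sum(cd$total == 0L), sum(cd$total)))
})
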