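#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

#' SpikeRecording: a multi-unit spike raster
#'
#' Container for the event (spike) times of one or more named signals
#' ("units") recorded simultaneously, together with the recording duration
#' and any experimental treatments administered during the recording.
#'
#' @slot trains named list of numeric vectors; each element holds one unit's
#'   event times in seconds, sorted non-decreasing, all >= 0. Duplicate
#'   timestamps within a unit are legal (they occur in real sorted data) and
#'   are retained.
#' @slot duration recording duration in seconds; at least the largest event
#'   time over all trains.
#' @slot treatments data.frame with columns \code{time} (seconds, within
#'   \code{[0, duration]}) and \code{label}.
#' @slot source free-text provenance string.
#'
#' @seealso [readRasterCSV()], [applyCleaning()], [correlogramSet()]
#' @export
setClass("SpikeRecording",
  slots = c(
    trains = "list",
    duration = "numeric",
    treatments = "data.frame",
    source = "character"
  )
)

setValidity("SpikeRecording", function(object) {
  msgs <- character()
  tr <- object@trains
  if (length(tr) < 1L) msgs <- c(msgs, "recording must contain at least one unit")
  ids <- names(tr)
  if (is.null(ids) || any(!nzchar(ids))) {
    msgs <- c(msgs, "all units must have nonempty ids")
  } else if (anyDuplicated(ids)) {
    msgs <- c(msgs, "unit ids must be unique")
  }
  for (i in seq_along(tr)) {
    x <- tr[[i]]
    if (!is.numeric(x)) { msgs <- c(msgs, "trains must be numeric"); break }
    if (length(x)) {
      if (anyNA(x) || any(!is.finite(x))) { msgs <- c(msgs, "event times must be finite"); break }
      if (any(x < 0)) { msgs <- c(msgs, "event times must be >= 0"); break }
      if (is.unsorted(x)) { msgs <- c(msgs, "event times must be sorted non-decreasing"); break }
    }
  }
  if (length(object@duration) != 1L || !is.finite(object@duration) || object@duration <= 0) {
    msgs <- c(msgs, "duration must be a single positive number")
  } else {
    mx <- suppressWarnings(max(0, unlist(tr, use.names = FALSE)))
    if (mx > object@duration) msgs <- c(msgs, "duration must be >= the largest event time")
  }
  tt <- object@treatments
  if (!all(c("time", "label") %in% names(tt))) {
    msgs <- c(msgs, "treatments must have columns 'time' and 'label'")
  } else if (nrow(tt) && (any(tt$time < 0) || any(tt$time > object@duration))) {
    msgs <- c(msgs, "treatment times must lie within [0, duration]")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a SpikeRecording
#'
#' Event times are sorted on construction so the canonical-order invariant
#' holds regardless of input order. If \code{duration} is omitted it defaults
#' to the largest event time.
#'
#' @param trains named list of numeric event-time vectors (seconds).
#' @param duration recording duration in seconds, or \code{NULL} to use the
#'   largest event time.
#' @param treatments data.frame with columns \code{time} and \code{label},
#'   or \code{NULL} for none.
#' @param source free-text provenance.
#' @return A [SpikeRecording-class] object.
#' @examples
#' rec <- SpikeRecording(list(a = c(0.3, 0.1), b = 0.2), duration = 1)
#' spikeTimes(rec, "a")
#' @export
SpikeRecording <- function(trains, duration = NULL, treatments = NULL,
                           source = "") {
  trains <- lapply(trains, function(x) sort(as.numeric(x)))
  if (is.null(duration)) {
    duration <- suppressWarnings(max(0, unlist(trains, use.names = FALSE)))
    if (duration <= 0) duration <- 1
  }
  if (is.null(treatments)) {
    treatments <- data.frame(time = numeric(), label = character())
  }
  treatments <- treatments[order(treatments$time), , drop = FALSE]
  rownames(treatments) <- NULL
  new("SpikeRecording", trains = trains, duration = as.numeric(duration),
      treatments = treatments, source = source)
}

#' CorrelogramSpec: binning geometry for correlograms
#'
#' Defines the lag window and bin width used when building correlograms.
#' Bin centers sit at integer multiples of the bin width so the center bin
#' always contains lag 0; with half-width \code{range} R and width w the bin
#' count is \code{2 * round(R / w) + 1}, which is odd by construction (e.g.
#' 2,001 bins for a +/- 1 s window at 1 ms).
#'
#' @slot range half-width R of the lag window in seconds (lags in [-R, +R]).
#' @slot binWidth bin width w in seconds.
#' @slot referenceSubset unit ids to use as reference signals, or
#'   \code{character(0)} for all units.
#' @export
setClass("CorrelogramSpec",
  slots = c(range = "numeric", binWidth = "numeric",
            referenceSubset = "character")
)

setValidity("CorrelogramSpec", function(object) {
  msgs <- character()
  R <- object@range; w <- object@binWidth
  if (length(R) != 1L || !is.finite(R) || R <= 0) msgs <- c(msgs, "range must be a positive number")
  if (length(w) != 1L || !is.finite(w) || w <= 0) msgs <- c(msgs, "binWidth must be a positive number")
  if (!length(msgs)) {
    if (w > 2 * R) msgs <- c(msgs, "binWidth must not exceed twice the range")
    if (2L * as.integer(round(R / w)) + 1L < 3L)
      msgs <- c(msgs, "bin geometry yields fewer than 3 bins")
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a CorrelogramSpec
#'
#' @param range half-width of the lag window in seconds. Default 1 s.
#' @param binWidth bin width in seconds. Default 1 ms, giving 2,001 bins at
#'   the default range. Ignored when \code{nBins} is supplied.
#' @param nBins optional odd bin count; the bin width is then derived as
#'   \code{2 * range / (nBins - 1)}.
#' @param referenceSubset optional character vector of unit ids to restrict
#'   reference signals to (perievent-style analysis).
#' @return A [CorrelogramSpec-class].
#' @examples
#' spec <- correlogramSpec(range = 1, binWidth = 0.001)
#' nBins(spec)  # 2001
#' @export
correlogramSpec <- function(range = 1, binWidth = 0.001, nBins = NULL,
                            referenceSubset = NULL) {
  if (!is.null(nBins)) {
    nBins <- as.integer(nBins)
    if (nBins < 3L || nBins %% 2L == 0L)
      stop("nBins must be an odd integer >= 3")
    binWidth <- 2 * range / (nBins - 1L)
  }
  new("CorrelogramSpec", range = as.numeric(range),
      binWidth = as.numeric(binWidth),
      referenceSubset = as.character(referenceSubset %||% character()))
}

#' Correlogram: binned relative-timing histogram for one signal pair
#'
#' Histogram of lags t = t_c - t_r between every comparison event t_c and
#' every reference event t_r that fall within one analysis region, with
#' |t| <= range. Normalizing the counts by their sum gives the probability
#' C(x) of a comparison event at lag x given a reference event at 0.
#'
#' @slot refId,cmpId unit ids of the reference and comparison signal.
#' @slot regionIndex 1-based index of the analysis region.
#' @slot binCenters bin-center lags in seconds, symmetric about 0.
#' @slot counts non-negative integer counts per bin.
#' @slot nRef,nCmp event counts of the reference and comparison train within
#'   the region.
#' @slot binWidth,range the geometry the correlogram was built with.
#' @export
setClass("Correlogram",
  slots = c(refId = "character", cmpId = "character",
            regionIndex = "integer", binCenters = "numeric",
            counts = "integer", nRef = "integer", nCmp = "integer",
            binWidth = "numeric", range = "numeric")
)

setValidity("Correlogram", function(object) {
  msgs <- character()
  L <- length(object@counts)
  if (L != length(object@binCenters)) msgs <- c(msgs, "counts and binCenters must have equal length")
  if (L < 3L || L %% 2L == 0L) msgs <- c(msgs, "bin count must be odd and >= 3")
  if (any(object@counts < 0L)) msgs <- c(msgs, "counts must be non-negative")
  if (L == length(object@binCenters) && L %% 2L == 1L) {
    if (abs(object@binCenters[(L + 1L) %/% 2L]) > 1e-12)
      msgs <- c(msgs, "center bin must sit at lag 0")
  }
  if (length(msgs)) msgs else TRUE
})

#' CorrelogramSet: all-pairs correlograms for one analysis region
#'
#' A \linkS4class{SummarizedExperiment} whose single \code{"counts"} assay is
#' the bins x pairs matrix of correlogram counts for every
#' (reference, comparison) pair in one analysis region. \code{rowData} holds
#' the bin-center lags; \code{colData} carries the pair bookkeeping
#' (\code{refId}, \code{cmpId}, \code{nRef}, \code{nCmp}, \code{nPairs},
#' \code{total}, \code{sparse}); \code{metadata} records the
#' [CorrelogramSpec-class], region and sparsity threshold. Units that fired
#' no events in the region still contribute (empty, sparse-flagged) columns
#' so pair matrices remain complete.
#'
#' @seealso [correlogramSet()], [correlogram()], [shapeMetrics()]
#' @export
setClass("CorrelogramSet", contains = "SummarizedExperiment")
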