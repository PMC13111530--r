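# Correlogram-independent recording statistics.

#' Per-unit firing counts, optionally per period
#'
#' Counts events per unit within each period (a period being the union of
#' its analysis regions) and normalizes by the period duration in minutes.
#' Without regions/periods a single all-covering period \code{"all"} is
#' used, so counts equal train lengths. Units with zero events are still
#' reported.
#'
#' @param rec a \linkS4class{SpikeRecording}.
#' @param regions,periods optional data.frames from [autoRegions()] /
#'   [assignPeriods()]; both or neither.
#' @return data.frame with columns \code{unit_id}, \code{period},
#'   \code{count}, \code{spikes_per_min}.
#' @export
firingCounts <- function(rec, regions = NULL, periods = NULL) {
  if (is.null(regions) != is.null(periods))
    stop("supply both regions and periods, or neither")
  if (is.null(regions)) {
    regions <- data.frame(index = 1L, start = 0, end = rec@duration,
                          label = "all")
    periods <- data.frame(index = 1L, period = factor("all"))
  }
  spans <- periodDurations(regions, periods)
  if (any(spans <= 0)) stop("zero-duration period")
  perOf <- periods$period[match(regions$index, periods$index)]
  out <- do.call(rbind, lapply(levels(factor(perOf)), function(p) {
    regs <- regions[perOf == p, , drop = FALSE]
    cnt <- vapply(rec@trains, function(x) {
      s <- 0L
      for (i in seq_len(nrow(regs)))
        s <- s + sum(x >= regs$start[i] & x < regs$end[i])
      s
    }, integer(1L))
    data.frame(unit_id = unitIds(rec), period = p, count = as.integer(cnt),
               spikes_per_min = cnt / (spans[[p]] / 60))
  }))
  rownames(out) <- NULL
  out
}

#' Interspike-interval histogram on log-spaced bins
#'
#' ISIs are the successive within-unit time differences. The histogram uses
#' log10-spaced bin edges over \code{range}; intervals outside the range
#' (including zero ISIs from duplicate timestamps) are clipped into the end
#' bins, and bin masses are normalized to probability.
#'
#' @param rec a \linkS4class{SpikeRecording}.
#' @param unit a unit id, or \code{NULL} to pool intervals over all units.
#' @param nBins number of log-spaced bins.
#' @param range \code{c(min_s, max_s)} span of the binning, seconds.
#' @return data.frame with columns \code{lower}, \code{upper}, \code{mid}
#'   (seconds) and \code{prob}; probabilities sum to 1. Attribute
#'   \code{"unit"} names the source ("pooled" when pooled).
#' @export
isiHistogram <- function(rec, unit = NULL, nBins = 50,
                         range = c(1e-4, 1e3)) {
  trains <- if (is.null(unit)) rec@trains else rec@trains[unit]
  isis <- unlist(lapply(trains, diff), use.names = FALSE)
  if (!length(isis)) stop("no intervals: all trains have fewer than 2 events")
  edges <- 10^seq(log10(range[1L]), log10(range[2L]), length.out = nBins + 1L)
  idx <- findInterval(isis, edges, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), nBins)  # clip out-of-range ISIs into end bins
  cnt <- tabulate(idx, nbins = nBins)
  out <- data.frame(lower = edges[-(nBins + 1L)], upper = edges[-1L],
                    mid = sqrt(edges[-(nBins + 1L)] * edges[-1L]),
                    prob = cnt / sum(cnt))
  attr(out, "unit") <- if (is.null(unit)) "pooled" else unit
  out
}

#' Spikes-per-minute trace with population mean and SD
#'
#' Counts each unit's events in consecutive 1-minute windows
#' \code{[60k, 60(k+1))} and summarizes the population with the per-window
#' mean and sample standard deviation (denominator N-1; 0 when N = 1). The
#' final window may be partial.
#'
#' @param rec a \linkS4class{SpikeRecording} of duration >= 1 minute.
#' @param window window length in seconds (default 60).
#' @return list with \code{counts} (units x windows integer matrix),
#'   \code{mean}, \code{sd} (per-window population summaries) and
#'   \code{windowStart} (seconds).
#' @export
rateTrace <- function(rec, window = 60) {
  if (rec@duration < window) stop("recording shorter than one window")
  nW <- max(1L, as.integer(ceiling(rec@duration / window - 1e-12)))
  counts <- t(vapply(rec@trains, function(x) {
    idx <- pmin(nW - 1L, floor(x / window))
    tabulate(idx + 1L, nbins = nW)
  }, integer(nW)))
  if (nW == 1L) counts <- matrix(counts, ncol = 1L)
  dimnames(counts) <- list(unitIds(rec), paste0("w", seq_len(nW) - 1L))
  m <- colMeans(counts)
  s <- if (nrow(counts) == 1L) rep(0, nW) else apply(counts, 2L, stats::sd)
  list(counts = counts, mean = m, sd = s,
       windowStart = (seq_len(nW) - 1L) * window)
}
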