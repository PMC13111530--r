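#' Automatic fixed-length analysis regions
#'
#' Divides \code{[0, duration)} into consecutive half-open regions
#' \code{[k*L, (k+1)*L)} of constant length. A trailing partial region
#' (remainder shorter than \code{regionLength}) is dropped, so the region
#' count is \code{floor(duration / regionLength)}: a 20.5 h recording cut
#' into 7 min regions yields 175 of them, a 1.7 h recording yields 14.
#'
#' @param duration recording duration in seconds.
#' @param regionLength region length in seconds (e.g. 420 for 7 min).
#' @return data.frame with columns \code{index}, \code{start}, \code{end},
#'   \code{label}; regions are ordered, non-overlapping and gap-free.
#' @examples
#' nrow(autoRegions(20.5 * 3600, 7 * 60))  # 175
#' @export
autoRegions <- function(duration, regionLength) {
  stopifnot(duration > 0, regionLength > 0)
  if (regionLength > duration)
    stop("recording shorter than one region")
  n <- floor(duration / regionLength + 1e-9)
  k <- seq_len(n) - 1
  data.frame(index = seq_len(n),
             start = k * regionLength,
             end = (k + 1) * regionLength,
             label = paste0("region_", seq_len(n)))
}

#' Manually specified analysis regions
#'
#' Regions are re-indexed 1..R in time order; overlapping or inverted bounds
#' are rejected.
#'
#' @param bounds data.frame with columns \code{start}, \code{end} (seconds)
#'   and optionally \code{label}, or a list of \code{c(start, end)} /
#'   \code{list(start, end, label)} entries.
#' @return data.frame as in [autoRegions()].
#' @export
manualRegions <- function(bounds) {
  if (!is.data.frame(bounds)) {
    bounds <- do.call(rbind, lapply(bounds, function(b) {
      data.frame(start = as.numeric(b[[1L]]), end = as.numeric(b[[2L]]),
                 label = if (length(b) >= 3L) as.character(b[[3L]]) else NA)
    }))
  }
  if (!all(c("start", "end") %in% names(bounds)))
    stop("bounds must provide start and end")
  if (is.null(bounds$label)) bounds$label <- NA
  if (any(bounds$start >= bounds$end))
    stop("validation error: region start must be < end")
  ord <- order(bounds$start)
  bounds <- bounds[ord, , drop = FALSE]
  if (nrow(bounds) > 1L &&
      any(bounds$start[-1L] < bounds$end[-nrow(bounds)]))
    stop("validation error: regions overlap")
  lab <- ifelse(is.na(bounds$label),
                paste0("region_", seq_len(nrow(bounds))), bounds$label)
  data.frame(index = seq_len(nrow(bounds)), start = bounds$start,
             end = bounds$end, label = lab)
}

#' Map analysis regions to before/after-treatment periods
#'
#' A region belongs to period \code{"after:X"} when treatment X was
#' administered before the region ends (\code{time < end}); the region
#' containing the treatment therefore counts as "after", since it already
#' holds the start of the response. With several treatments the latest
#' applicable label wins. Regions preceding all treatments are labelled
#' \code{"before:<first treatment>"}; with no treatments every region maps
#' to the single period \code{"all"}.
#'
#' @param regions data.frame from [autoRegions()] / [manualRegions()].
#' @param treatments data.frame with columns \code{time}, \code{label}
#'   (sorted by time), e.g. from [treatments()].
#' @param duration recording duration used to validate treatment times;
#'   defaults to the last region end.
#' @return data.frame with columns \code{index}, \code{period}; the
#'   \code{period} column is a factor whose levels follow first occurrence.
#' @examples
#' reg <- autoRegions(14 * 420, 420)
#' tr <- data.frame(time = 8.2 * 420, label = "bicuculline")
#' table(assignPeriods(reg, tr)$period)  # 8 before, 6 after
#' @export
assignPeriods <- function(regions, treatments = NULL,
                          duration = max(regions$end)) {
  if (is.null(treatments) || nrow(treatments) == 0L) {
    per <- rep("all", nrow(regions))
  } else {
    if (any(treatments$time < 0) || any(treatments$time > duration))
      stop("treatment time outside [0, duration]")
    treatments <- treatments[order(treatments$time), , drop = FALSE]
    per <- vapply(seq_len(nrow(regions)), function(i) {
      applicable <- which(treatments$time < regions$end[i])
      if (!length(applicable)) paste0("before:", treatments$label[1L])
      else paste0("after:", treatments$label[max(applicable)])
    }, character(1L))
  }
  data.frame(index = regions$index,
             period = factor(per, levels = unique(per)))
}

#' Per-period time spans
#'
#' Total duration (seconds) covered by the regions of each period; used to
#' normalize firing counts to spikes per minute.
#'
#' @param regions,periods as in [assignPeriods()].
#' @return named numeric vector of seconds per period.
#' @export
periodDurations <- function(regions, periods) {
  spans <- regions$end - regions$start
  tapply(spans, periods$period[match(regions$index, periods$index)], sum)
}
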