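#' Read a multi-unit spike raster from long-format CSV
#'
#' The native input format is a plain long CSV with header
#' \code{unit_id,time_s}, UTF-8, one event per row, in any row order.
#' One \code{SpikeTrain} is created per distinct \code{unit_id}; times are
#' sorted on construction, so row order in the file is irrelevant. Vendor
#' formats (e.g. Plexon .plx) are supported through the adapter hook of
#' [readRecording()].
#'
#' @param path path to the CSV file.
#' @param duration optional recording duration in seconds; defaults to the
#'   largest event time in the file.
#' @param treatments optional data.frame of treatment events
#'   (\code{time}, \code{label}).
#' @return A \linkS4class{SpikeRecording}.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("unit_id,time_s", "a,0.2", "a,0.1", "b,0.15"), f)
#' rec <- readRasterCSV(f)
#' spikeTimes(rec, "a")  # 0.1 0.2
#' @export
readRasterCSV <- function(path, duration = NULL, treatments = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  if (!identical(trimws(header), "unit_id,time_s"))
    stop("format error: expected header 'unit_id,time_s', got '", header, "'")
  df <- utils::read.csv(path, colClasses = c("character", "character"),
                        strip.white = TRUE)
  if (nrow(df) == 0L) stop("no events: file body is empty")
  times <- suppressWarnings(as.numeric(df$time_s))
  bad <- which(is.na(times) | !is.finite(times) | times < 0)
  if (length(bad)) {
    stop("validation error: non-finite or negative time_s at data row ",
         bad[1L], " ('", df$time_s[bad[1L]], "')")
  }
  trains <- split(times, df$unit_id)
  SpikeRecording(trains, duration = duration, treatments = treatments,
                 source = path)
}

#' Read a recording through a format adapter
#'
#' Adapter hook for vendor file formats: any function that takes a path and
#' returns a \linkS4class{SpikeRecording} (e.g. a user-supplied Plexon .plx
#' reader) can stand in for the native CSV reader, and everything downstream
#' is format-agnostic.
#'
#' @param path input file path, passed to the adapter.
#' @param reader a function \code{function(path, ...) -> SpikeRecording};
#'   defaults to [readRasterCSV()].
#' @param ... forwarded to the adapter.
#' @return A \linkS4class{SpikeRecording}.
#' @export
readRecording <- function(path, reader = readRasterCSV, ...) {
  rec <- reader(path, ...)
  if (!methods::is(rec, "SpikeRecording"))
    stop("adapter must return a SpikeRecording")
  rec
}

#' Write a recording back to the long CSV format
#'
#' Times are written as fixed-precision decimal strings (9 decimal places),
#' so a write/read/write round trip reproduces the file byte for byte.
#'
#' @param rec a \linkS4class{SpikeRecording}.
#' @param path output path.
#' @param digits decimal places for event times.
#' @return \code{path}, invisibly.
#' @export
writeRasterCSV <- function(rec, path, digits = 9) {
  ids <- rep(unitIds(rec), lengths(rec@trains))
  tms <- unlist(rec@trains, use.names = FALSE)
  lines <- c("unit_id,time_s",
             if (length(tms)) paste0(ids, ",", formatC(tms, format = "f",
                                                       digits = digits)))
  writeLines(lines, path)
  invisible(path)
}

#' Remove excluded time windows and unwanted units from a recording
#'
#' Events inside any excluded half-open window \code{[start, end)} are
#' dropped, as are whole trains named in \code{removedUnits}. Remaining
#' event times are not shifted (the absolute clock is preserved) and the
#' recording duration is unchanged, so analysis regions keep their meaning;
#' a region overlapping an excluded window simply contains fewer events.
#' The operation is idempotent.
#'
#' @param rec a \linkS4class{SpikeRecording}.
#' @param excludedWindows list of numeric \code{c(start, end)} pairs (or a
#'   2-column matrix), each within \code{[0, duration]} with start < end.
#' @param removedUnits character vector of unit ids to drop; ids not present
#'   raise a warning, not an error.
#' @return The cleaned \linkS4class{SpikeRecording}.
#' @examples
#' rec <- SpikeRecording(list(a = c(1, 5, 9)), duration = 10)
#' spikeTimes(applyCleaning(rec, excludedWindows = list(c(4, 6))), "a")  # 1 9
#' @export
applyCleaning <- function(rec, excludedWindows = NULL, removedUnits = character()) {
  wins <- .normalizeWindows(excludedWindows, rec@duration)
  removedUnits <- as.character(removedUnits)
  missing <- setdiff(removedUnits, unitIds(rec))
  if (length(missing))
    warning("removed unit(s) not present in recording: ",
            paste(missing, collapse = ", "))
  trains <- rec@trains[setdiff(unitIds(rec), removedUnits)]
  if (!length(trains)) stop("empty recording: all units removed")
  if (nrow(wins)) {
    trains <- lapply(trains, function(x) {
      keep <- rep(TRUE, length(x))
      for (i in seq_len(nrow(wins)))
        keep <- keep & !(x >= wins[i, 1L] & x < wins[i, 2L])
      x[keep]
    })
  }
  if (sum(lengths(trains)) == 0L)
    stop("empty recording: cleaning removed every event")
  SpikeRecording(trains, duration = rec@duration,
                 treatments = rec@treatments, source = rec@source)
}

.normalizeWindows <- function(excludedWindows, duration) {
  if (is.null(excludedWindows) || !length(excludedWindows))
    return(matrix(numeric(), ncol = 2L))
  if (is.matrix(excludedWindows)) {
    wins <- excludedWindows
  } else {
    wins <- do.call(rbind, lapply(excludedWindows, function(w) {
      if (length(w) != 2L) stop("each excluded window must be c(start, end)")
      as.numeric(w)
    }))
  }
  if (any(wins[, 1L] >= wins[, 2L]))
    stop("excluded windows must have start < end")
  if (any(wins[, 1L] < 0) || any(wins[, 2L] > duration))
    stop("excluded windows must lie within [0, duration]")
  wins
}

#' Per-window activity flags for each unit
#'
#' A unit counts as active in a window when it fired at least
#' \code{minSpikes} events there; the conventional criterion is at least 10
#' spikes per minute. Windows are half-open \code{[k*window, (k+1)*window)}
#' and tile the whole recording (the final window may be partial).
#'
#' @param rec a \linkS4class{SpikeRecording}.
#' @param window window length in seconds (default 60, i.e. per-minute).
#' @param minSpikes activity threshold (default 10).
#' @return Logical matrix, units x windows.
#' @export
activeUnitMask <- function(rec, window = 60, minSpikes = 10) {
  stopifnot(window > 0, minSpikes >= 0)
  nW <- max(1L, as.integer(ceiling(rec@duration / window - 1e-12)))
  counts <- t(vapply(rec@trains, function(x) {
    idx <- pmin(nW - 1L, floor(x / window))
    tabulate(idx + 1L, nbins = nW)
  }, integer(nW)))
  if (nW == 1L) counts <- matrix(counts, ncol = 1L,
                                 dimnames = list(unitIds(rec), NULL))
  mask <- counts >= minSpikes
  dimnames(mask) <- list(unitIds(rec),
                         paste0("w", seq_len(nW) - 1L))
  mask
}
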