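# Correlogram construction: the paper-of-record binning semantics live here.

#' Bin edges and centers for a correlogram geometry
#'
#' Centers sit at \code{k * w} for \code{k = -K..K} with
#' \code{K = round(range / w)}, so the center bin always contains lag 0 and
#' the bin count \code{2K + 1} is odd; edges sit halfway between centers.
#'
#' @param spec a \linkS4class{CorrelogramSpec}.
#' @return list with \code{centers}, \code{edges} (seconds) and \code{nBins}.
#' @examples
#' makeBins(correlogramSpec(1, 0.001))$nBins  # 2001
#' @export
makeBins <- function(spec) {
  K <- as.integer(round(spec@range / spec@binWidth))
  L <- 2L * K + 1L
  if (L < 3L) stop("bin geometry yields fewer than 3 bins")
  centers <- (-K:K) * spec@binWidth
  edges <- c(centers - spec@binWidth / 2, centers[L] + spec@binWidth / 2)
  list(centers = centers, edges = edges, nBins = L)
}

#' Signed bin index for a lag
#'
#' Assigns a lag to the nearest bin center (centers at integer multiples of
#' the bin width); a lag landing exactly on a bin edge, i.e. halfway between
#' two centers, is resolved toward zero. With 1 ms bins a comparison event
#' 2.5 ms after the reference falls in bin 2, and one 6.5 ms before the
#' reference in bin -6. Lags beyond \code{range + binWidth/2} return
#' \code{NA} (excluded).
#'
#' @param lag numeric vector of lags \code{t_c - t_r} in seconds.
#' @param binWidth bin width in seconds.
#' @param range optional half-width of the lag window; when supplied, lags
#'   outside \code{[-range - binWidth/2, range + binWidth/2]} map to NA.
#' @return integer vector of signed bin indices (0 = center bin).
#' @examples
#' assignBin(c(0.0025, -0.0065, 0), 0.001)  # 2 -6 0
#' @export
assignBin <- function(lag, binWidth, range = NULL) {
  stopifnot(binWidth > 0)
  q <- abs(lag) / binWidth
  fl <- floor(q)
  frac <- q - fl
  tol <- 1e-9
  k <- ifelse(abs(frac - 0.5) <= tol, fl, floor(q + 0.5))
  idx <- as.integer(sign(lag) * k)
  if (!is.null(range))
    idx[abs(lag) > range + binWidth / 2 + tol * binWidth] <- NA_integer_
  idx
}

# Vectorized all-pairs lag histogram for two sorted time vectors.
# Only pairs with |t_c - t_r| <= R contribute; each reference event's
# comparison window is located with findInterval, so cost is
# O((n_ref + n_cmp) log + S) rather than O(n_ref * n_cmp).
.correlogramCounts <- function(refT, cmpT, R, w) {
  K <- as.integer(round(R / w))
  L <- 2L * K + 1L
  if (!length(refT) || !length(cmpT)) return(integer(L))
  lo <- findInterval(refT - R, cmpT, left.open = TRUE) + 1L # first cmp >= t_r - R
  hi <- findInterval(refT + R, cmpT)                        # last  cmp <= t_r + R
  n <- hi - lo + 1L
  keep <- n > 0L
  if (!any(keep)) return(integer(L))
  cmpIdx <- sequence(n[keep], from = lo[keep])
  refIdx <- rep.int(which(keep), n[keep])
  lags <- cmpT[cmpIdx] - refT[refIdx]
  k <- assignBin(lags, w)
  tabulate(k + K + 1L, nbins = L)
}

#' Build the correlogram of one (reference, comparison) pair
#'
#' Uses only events with \code{region$start <= t < region$end}; for every
#' reference event \code{t_r} and comparison event \code{t_c} with
#' \code{|t_c - t_r| <= range} the bin at \code{assignBin(t_c - t_r)} is
#' incremented. Pairs spanning a region boundary are not counted: each
#' region is self-contained. For autocorrelograms (\code{refId == cmpId})
#' the pairing of an event with itself is excluded, since a self-pair
#' carries no timing information; coincident events of two different units
#' are counted.
#'
#' @param ref,cmp reference and comparison input: either two unit ids (with
#'   \code{rec} a \linkS4class{SpikeRecording}) or two numeric time vectors.
#' @param spec a \linkS4class{CorrelogramSpec}.
#' @param region one row of an [autoRegions()] frame (or \code{NULL} for the
#'   whole recording).
#' @param rec the recording, when \code{ref}/\code{cmp} are unit ids.
#' @param refId,cmpId labels used when \code{ref}/\code{cmp} are numeric.
#' @return A \linkS4class{Correlogram}. Empty trains yield a correlogram
#'   with total 0, flagged sparse.
#' @examples
#' spec <- correlogramSpec(range = 1, binWidth = 0.001)
#' cg <- buildCorrelogram(c(0, 0.5), c(0.1, 0.6, 2.0), spec,
#'                        refId = "a", cmpId = "b")
#' totalEvents(cg)  # 4: lags 0.1, 0.6, -0.4, 0.1; 1.5 and 2.0 out of range
#' @export
buildCorrelogram <- function(ref, cmp, spec, region = NULL, rec = NULL,
                             refId = NULL, cmpId = NULL) {
  if (is.character(ref)) {
    stopifnot(!is.null(rec))
    refId <- ref; cmpId <- cmp
    ref <- spikeTimes(rec, refId)
    cmp <- spikeTimes(rec, cmpId)
  } else {
    refId <- refId %||% "ref"
    cmpId <- cmpId %||% "cmp"
  }
  regionIndex <- 1L
  if (!is.null(region)) {
    regionIndex <- as.integer(region$index %||% 1L)
    ref <- ref[ref >= region$start & ref < region$end]
    cmp <- cmp[cmp >= region$start & cmp < region$end]
  }
  bins <- makeBins(spec)
  cnt <- .correlogramCounts(ref, cmp, spec@range, spec@binWidth)
  auto <- identical(refId, cmpId)
  if (auto && length(ref)) {
    # remove the lag-0 self-pairs (one per event)
    cnt[(bins$nBins + 1L) %/% 2L] <- cnt[(bins$nBins + 1L) %/% 2L] - length(ref)
  }
  new("Correlogram", refId = refId, cmpId = cmpId,
      regionIndex = regionIndex, binCenters = bins$centers,
      counts = as.integer(cnt), nRef = length(ref), nCmp = length(cmp),
      binWidth = spec@binWidth, range = spec@range)
}

#' All-pairs correlograms for one analysis region
#'
#' Builds the correlogram of every (reference, comparison) pair of units in
#' the region -- all N^2 pairs, or \code{length(referenceSubset) * N} when
#' the spec restricts the reference signals (perievent-style analysis).
#' Units with zero events in the region still yield empty, sparse-flagged
#' correlograms, so pair matrices stay complete.
#'
#' @param rec a \linkS4class{SpikeRecording}.
#' @param region one row of an [autoRegions()] frame, or \code{NULL} for the
#'   whole recording.
#' @param spec a \linkS4class{CorrelogramSpec}.
#' @param sparsityThreshold raster-event product at or below which a pair is
#'   flagged sparse (see [isSparse()]).
#' @return A \linkS4class{CorrelogramSet}.
#' @export
correlogramSet <- function(rec, region = NULL, spec = correlogramSpec(),
                           sparsityThreshold = 0) {
  ids <- unitIds(rec)
  refs <- if (length(spec@referenceSubset)) {
    bad <- setdiff(spec@referenceSubset, ids)
    if (length(bad)) stop("unknown reference unit(s): ",
                          paste(bad, collapse = ", "))
    spec@referenceSubset
  } else ids
  bins <- makeBins(spec)
  regionIndex <- if (is.null(region)) 1L else as.integer(region$index %||% 1L)
  clipped <- lapply(rec@trains, function(x) {
    if (is.null(region)) x else x[x >= region$start & x < region$end]
  })
  nEv <- lengths(clipped)
  ctr <- (bins$nBins + 1L) %/% 2L
  nPairsTotal <- length(refs) * length(ids)
  counts <- matrix(0L, nrow = bins$nBins, ncol = nPairsTotal)
  refCol <- character(nPairsTotal); cmpCol <- character(nPairsTotal)
  j <- 0L
  for (r in refs) {
    for (cpy in ids) {
      j <- j + 1L
      refCol[j] <- r; cmpCol[j] <- cpy
      cnt <- .correlogramCounts(clipped[[r]], clipped[[cpy]],
                                spec@range, spec@binWidth)
      if (identical(r, cpy) && nEv[[r]] > 0L) cnt[ctr] <- cnt[ctr] - nEv[[r]]
      counts[, j] <- cnt
    }
  }
  tot <- colSums(counts)
  cd <- S4Vectors::DataFrame(
    refId = refCol, cmpId = cmpCol, regionIndex = regionIndex,
    nRef = as.integer(nEv[refCol]), nCmp = as.integer(nEv[cmpCol]),
    nPairs = as.numeric(nEv[refCol]) * as.numeric(nEv[cmpCol]),
    total = as.integer(tot))
  cd$sparse <- cd$nPairs <= sparsityThreshold | cd$total == 0L
  colnames(counts) <- paste(refCol, cmpCol, sep = "|")
  rownames(cd) <- colnames(counts)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(binCenter = bins$centers),
    colData = cd,
    metadata = list(spec = spec, region = region,
                    sparsityThreshold = sparsityThreshold))
  new("CorrelogramSet", se)
}

#' Extract one pair's Correlogram from a CorrelogramSet
#'
#' @param cset a \linkS4class{CorrelogramSet}.
#' @param refId,cmpId unit ids of the pair.
#' @return A \linkS4class{Correlogram}.
#' @export
correlogram <- function(cset, refId, cmpId) {
  key <- paste(refId, cmpId, sep = "|")
  if (!key %in% colnames(cset)) stop("pair not present: ", key)
  cd <- colData(cset)[key, ]
  spec <- metadata(cset)$spec
  new("Correlogram", refId = refId, cmpId = cmpId,
      regionIndex = as.integer(cd$regionIndex),
      binCenters = rowData(cset)$binCenter,
      counts = as.integer(assay(cset, "counts")[, key]),
      nRef = cd$nRef, nCmp = cd$nCmp,
      binWidth = spec@binWidth, range = spec@range)
}
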