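# Categorical classification of the three shape metrics, plus the
# fraction / transition / combined-combination summaries built on them.

.LF_LEVELS <- c("weak", "fairly_weak", "intermediate", "fairly_strong",
                "strong")
.UNIF_LEVELS <- c("uniform", "nonuniform")

#' Classify uniformity from the test p-value
#'
#' Uniform iff \code{p > alpha}; a p-value exactly at the cutoff is
#' nonuniform.
#'
#' @param pValue numeric vector of p-values in \code{[0, 1]}.
#' @param alpha significance cutoff (default 0.05).
#' @return factor with levels \code{uniform, nonuniform}.
#' @export
classifyUniformity <- function(pValue, alpha = 0.05) {
  stopifnot(all(is.na(pValue) | (pValue >= 0 & pValue <= 1)))
  factor(ifelse(pValue > alpha, "uniform", "nonuniform"),
         levels = .UNIF_LEVELS)
}

#' Classify peak count with a user ceiling
#'
#' Counts below the user maximum M keep their own class; counts at or above
#' M collapse into the ceiling class \code{"M+"}, giving M + 1 classes in
#' total (e.g. 0, 1, 2, 3, "4+" for M = 4).
#'
#' @param count integer vector of peak counts (>= 0).
#' @param maxPeaks user ceiling M (>= 1).
#' @return factor with levels \code{0, ..., M-1, "M+"}.
#' @export
classifyPeakCount <- function(count, maxPeaks = 4L) {
  stopifnot(maxPeaks >= 1)
  M <- as.integer(maxPeaks)
  lev <- c(as.character(seq_len(M) - 1L), paste0(M, "+"))
  factor(ifelse(is.na(count), NA,
                ifelse(count >= M, paste0(M, "+"), as.character(count))),
         levels = lev)
}

#' Classify peak times by timescale or frequency band
#'
#' In \code{"timescale"} mode, absolute peak times fall into log-decade
#' classes anchored at the correlogram range R: for R = 1 s and the default
#' floor R/1000, the four classes are |t| <= 1 ms, (1, 10] ms,
#' (10, 100] ms and (100 ms, 1 s]. A lag of exactly 0 belongs to the
#' smallest class. In \code{"frequency"} mode, \code{f = 1/|t|} falls into
#' contiguous half-open EEG-style bands: delta [0, 4), theta [4, 8),
#' alpha [8, 13), beta [13, 32), gamma [32, Inf) Hz -- e.g. |t| = 0.2 s is
#' 5 Hz, theta. Zero lags are excluded from frequency classing (f is
#' undefined there).
#'
#' @param times numeric vector of signed peak times (seconds), all within
#'   \code{[-range, range]}.
#' @param mode \code{"timescale"} or \code{"frequency"}.
#' @param range correlogram half-width R in seconds.
#' @param floor smallest timescale-class edge; default \code{range / 1000}.
#' @return factor of class labels (zero lags dropped in frequency mode).
#' @export
classifyPeakTimes <- function(times, mode = c("timescale", "frequency"),
                              range = 1, floor = range / 1000) {
  mode <- match.arg(mode)
  at <- abs(times)
  if (any(at > range + 1e-12)) stop("peak times must lie within [-range, range]")
  if (mode == "timescale") {
    D <- max(1L, as.integer(round(log10(range / floor))))
    edges <- range / 10^(D:0)          # ascending: floor ... range
    lev <- c(sprintf("<=%.3gs", edges[1L]),
             sprintf("(%.3g,%.3g]s", edges[-(D + 1L)], edges[-1L]))
    idx <- findInterval(at, edges, left.open = TRUE) + 1L
    idx <- pmin(idx, D + 1L)           # |t| == range lands in the top class
    factor(lev[idx], levels = lev)
  } else {
    at <- at[at > 0]
    f <- 1 / at
    cut(f, breaks = c(0, 4, 8, 13, 32, Inf), right = FALSE,
        labels = c("delta", "theta", "alpha", "beta", "gamma"))
  }
}

#' Classify leader/follower strength from area left of zero
#'
#' The five classes partition \code{[0, 1]} symmetrically about 0.5, so the
#' two mirrored correlograms of a pair (with \code{A' = 1 - A}) always land
#' in the same class: weak for \code{0.4 < A < 0.6}; fairly weak for
#' \code{0.6 <= A < 0.7} or \code{0.3 < A <= 0.4}; intermediate for
#' \code{0.7 <= A < 0.8} or \code{0.2 < A <= 0.3}; fairly strong for
#' \code{0.8 <= A < 0.9} or \code{0.1 < A <= 0.2}; strong for
#' \code{A >= 0.9} or \code{A <= 0.1}.
#'
#' @param A numeric vector in \code{[0, 1]}.
#' @return factor with the five strength levels.
#' @export
classifyLeaderFollower <- function(A) {
  ok <- is.na(A) | (A >= 0 & A <= 1)
  if (!all(ok)) stop("A must lie in [0, 1]")
  cls <- ifelse(A > 0.4 & A < 0.6, "weak",
         ifelse((A >= 0.6 & A < 0.7) | (A > 0.3 & A <= 0.4), "fairly_weak",
         ifelse((A >= 0.7 & A < 0.8) | (A > 0.2 & A <= 0.3), "intermediate",
         ifelse((A >= 0.8 & A < 0.9) | (A > 0.1 & A <= 0.2), "fairly_strong",
                "strong"))))
  factor(cls, levels = .LF_LEVELS)
}

#' Classify every correlogram in a metrics table
#'
#' Applies the three classification schemes to a [shapeMetrics()] table.
#' Sparse correlograms carry no classes (NA).
#'
#' @param metrics data.frame from [shapeMetrics()] (rows from several
#'   regions may be bound together).
#' @param alpha uniformity cutoff.
#' @param maxPeaks peak-count ceiling M.
#' @param peakTimeMode \code{"timescale"} or \code{"frequency"}.
#' @param range correlogram half-width (seconds), for peak-time classes.
#' @return the input with added columns \code{uniformity_class},
#'   \code{peak_class}, \code{lf_class}, \code{peak_time_classes}
#'   (semicolon-joined labels).
#' @export
classifyCorrelograms <- function(metrics, alpha = 0.05, maxPeaks = 4L,
                                 peakTimeMode = "timescale", range = 1) {
  metrics$uniformity_class <- classifyUniformity(metrics$p_value, alpha)
  metrics$peak_class <- classifyPeakCount(metrics$peak_count, maxPeaks)
  metrics$lf_class <- classifyLeaderFollower(metrics$area_left)
  metrics$peak_time_classes <- vapply(metrics$peak_times, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    tms <- as.numeric(strsplit(s, ";", fixed = TRUE)[[1L]])
    paste(as.character(classifyPeakTimes(tms, peakTimeMode, range = range)),
          collapse = ";")
  }, character(1L), USE.NAMES = FALSE)
  metrics
}

.schemeColumn <- function(scheme) {
  switch(scheme, uniformity = "uniformity_class", peaks = "peak_class",
         lf = "lf_class", stop("unknown scheme: ", scheme))
}

.usableRecords <- function(records, includeAutocorrelograms) {
  keep <- !records$sparse
  if (!includeAutocorrelograms) keep <- keep & records$ref_id != records$cmp_id
  records[keep, , drop = FALSE]
}

#' Per-region class fractions
#'
#' Fraction of (non-sparse) correlograms in each class of one scheme, per
#' analysis region. Autocorrelograms are excluded by default. Regions whose
#' correlograms are all sparse are emitted with NA fractions.
#'
#' @param records classified table from [classifyCorrelograms()].
#' @param scheme \code{"uniformity"}, \code{"peaks"} or \code{"lf"}.
#' @param includeAutocorrelograms include self-pairs?
#' @return long data.frame \code{region, class, fraction, n}; fractions of
#'   each region sum to 1 (or are NA).
#' @export
classFractions <- function(records, scheme = "uniformity",
                           includeAutocorrelograms = FALSE) {
  col <- .schemeColumn(scheme)
  regions <- sort(unique(records$region))
  usable <- .usableRecords(records, includeAutocorrelograms)
  lev <- levels(records[[col]])
  out <- do.call(rbind, lapply(regions, function(r) {
    cls <- usable[[col]][usable$region == r]
    n <- length(cls)
    frac <- if (n) as.numeric(table(factor(cls, levels = lev))) / n
            else rep(NA_real_, length(lev))
    data.frame(region = r, class = factor(lev, levels = lev),
               fraction = frac, n = n)
  }))
  rownames(out) <- NULL
  out
}

#' Classification transition probabilities
#'
#' For each consecutive region pair (r-1, r) and each correlogram identity
#' (refId, cmpId) present and non-sparse at both endpoints, tallies the
#' transition class(r-1) -> class(r); sparse endpoints are skipped, not
#' imputed, and the skipped-step count is reported as an attribute. Rows
#' are normalized to conditional probabilities, so the table answers: given
#' a correlogram's class in the previous region, how likely is each class
#' in the current one?
#'
#' @param records classified table covering >= 2 regions.
#' @param scheme \code{"uniformity"}, \code{"peaks"} or \code{"lf"}.
#' @param step \code{"region"} gives one table per step r-1 -> r (labelled
#'   by destination region); \code{"period"} pools steps by the period of
#'   the destination region, so the step crossing a treatment belongs to
#'   "after".
#' @param periods data.frame from [assignPeriods()] (required for
#'   \code{step = "period"}).
#' @param includeAutocorrelograms include self-pairs?
#' @return long data.frame \code{grouping, from_class, to_class,
#'   probability, support}; within each grouping, rows of each observed
#'   \code{from_class} sum to 1. Attribute \code{"skipped"} counts steps
#'   dropped for sparsity.
#' @export
transitionProbabilities <- function(records, scheme = "uniformity",
                                    step = c("region", "period"),
                                    periods = NULL,
                                    includeAutocorrelograms = FALSE) {
  step <- match.arg(step)
  col <- .schemeColumn(scheme)
  if (step == "period" && is.null(periods))
    stop("periods required for step = 'period'")
  keep <- if (includeAutocorrelograms) rep(TRUE, nrow(records))
          else records$ref_id != records$cmp_id
  rr <- records[keep, , drop = FALSE]
  regions <- sort(unique(rr$region))
  if (length(regions) < 2L) stop("need at least 2 regions")
  lev <- levels(rr[[col]])
  rr$pairKey <- paste(rr$ref_id, rr$cmp_id, sep = "|")
  skipped <- 0L
  steps <- list()
  for (i in seq_along(regions)[-1L]) {
    r0 <- regions[i - 1L]; r1 <- regions[i]
    a <- rr[rr$region == r0, c("pairKey", "sparse", col)]
    b <- rr[rr$region == r1, c("pairKey", "sparse", col)]
    m <- merge(a, b, by = "pairKey", suffixes = c(".from", ".to"))
    drop <- m$sparse.from | m$sparse.to
    skipped <- skipped + sum(drop)
    m <- m[!drop, , drop = FALSE]
    if (!nrow(m)) next
    grp <- if (step == "region") paste0("to_region_", r1) else
      as.character(periods$period[match(r1, periods$index)])
    steps[[length(steps) + 1L]] <- data.frame(
      grouping = grp,
      from_class = factor(m[[paste0(col, ".from")]], levels = lev),
      to_class = factor(m[[paste0(col, ".to")]], levels = lev))
  }
  tallies <- do.call(rbind, steps)
  out <- do.call(rbind, lapply(unique(tallies$grouping), function(g) {
    tt <- table(tallies$from_class[tallies$grouping == g],
                tallies$to_class[tallies$grouping == g])
    sup <- rowSums(tt)
    pr <- tt / ifelse(sup > 0, sup, 1)
    df <- as.data.frame(as.table(pr), stringsAsFactors = FALSE)
    names(df) <- c("from_class", "to_class", "probability")
    df$support <- as.numeric(sup[df$from_class])
    df$probability[df$support == 0] <- NA_real_
    cbind(grouping = g, df)
  }))
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Combined classification combinations
#'
#' Percent of correlograms in each cell of the full
#' uniformity x leader/follower x peak-count grid --
#' \code{2 * 5 * (M + 1)} cells (110 for M = 10) -- per grouping
#' (\code{"all"}, or the period of each region when \code{periods} is
#' given). Cell percentages of each grouping sum to 100.
#'
#' @param records classified table from [classifyCorrelograms()].
#' @param periods optional [assignPeriods()] frame to group regions into
#'   periods.
#' @param includeAutocorrelograms include self-pairs?
#' @return data.frame \code{grouping, uniformity_class, lf_class,
#'   peak_class, n, percent} with one row per cell.
#' @export
combinedComboTable <- function(records, periods = NULL,
                               includeAutocorrelograms = FALSE) {
  usable <- .usableRecords(records, includeAutocorrelograms)
  usable$grouping <- if (is.null(periods)) "all" else
    as.character(periods$period[match(usable$region, periods$index)])
  grid <- expand.grid(uniformity_class = levels(records$uniformity_class),
                      lf_class = levels(records$lf_class),
                      peak_class = levels(records$peak_class),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- do.call(rbind, lapply(unique(usable$grouping), function(g) {
    sub <- usable[usable$grouping == g, ]
    key <- paste(sub$uniformity_class, sub$lf_class, sub$peak_class)
    tab <- table(factor(key, levels = paste(grid$uniformity_class,
                                            grid$lf_class, grid$peak_class)))
    n <- as.numeric(tab)
    cbind(grouping = g, grid, n = n,
          percent = if (sum(n)) 100 * n / sum(n) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
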