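# The three correlogram shape metrics: uniformity, peaks, area left of zero.

#' Metric parameters
#'
#' Bundles the tunables of the shape-metric stage.
#'
#' @param alpha significance cutoff for the uniformity test; a correlogram
#'   is uniform iff its p-value exceeds \code{alpha} (default 0.05).
#' @param smoothWindow odd number of bins W for the pre-peak-detection
#'   smoother; 1 disables smoothing.
#' @param minProminence prominence a peak must strictly exceed; \code{NULL}
#'   uses \code{1/L} (the height scale of a uniform correlogram), computed
#'   per correlogram.
#' @param chi2Variant \code{"pearson"} (default) uses Pearson's
#'   \code{sum((O - E)^2 / E)}, whose upper tail genuinely follows a
#'   chi-squared law with L-1 degrees of freedom; \code{"as_printed"} uses
#'   the unscaled \code{sum((O - E)^2)} for comparison with the original
#'   MATLAB implementation's output.
#' @param centerBin \code{"split"} (default) assigns half the center-bin
#'   mass to the area left of zero so the complementarity identity
#'   \code{A_ji = 1 - A_ij} holds exactly; \code{"exclude"} drops the
#'   center-bin mass from A entirely.
#' @return list of validated parameters, class \code{"MetricParams"}.
#' @export
metricParams <- function(alpha = 0.05, smoothWindow = 1L,
                         minProminence = NULL,
                         chi2Variant = c("pearson", "as_printed"),
                         centerBin = c("split", "exclude")) {
  stopifnot(alpha > 0, alpha < 1, smoothWindow >= 1)
  if (smoothWindow %% 2 == 0) stop("smoothWindow must be odd")
  if (!is.null(minProminence) && minProminence <= 0)
    stop("minProminence must be positive")
  structure(list(alpha = alpha, smoothWindow = as.integer(smoothWindow),
                 minProminence = minProminence,
                 chi2Variant = match.arg(chi2Variant),
                 centerBin = match.arg(centerBin)),
            class = "MetricParams")
}

#' Chi-squared test of correlogram uniformity
#'
#' Tests the binned correlogram against a flat histogram: two independent
#' signals produce a uniform correlogram with \code{C(x) = 1/L} in every
#' bin. With observed counts \code{O_x = S * C(x)} and expected count
#' \code{E = S/L}, the default Pearson statistic is
#' \code{sum((O_x - E)^2 / E)}; the p-value is the upper tail of the
#' chi-squared distribution with L-1 degrees of freedom. The correlogram is
#' uniform iff \code{p > alpha} (nonuniform at \code{p == alpha}). An
#' expected count below 5 degrades the chi-squared approximation; the
#' result then carries a warning flag rather than being refused.
#'
#' @param cg a non-sparse \linkS4class{Correlogram}, or an integer count
#'   vector.
#' @param alpha significance cutoff.
#' @param variant \code{"pearson"} or \code{"as_printed"} (see
#'   [metricParams()]).
#' @return list with \code{chi2}, \code{pValue}, \code{uniform} and
#'   \code{expectedCountWarning}.
#' @examples
#' chiSquaredUniformity(c(10, 0, 0, 0))$chi2  # 30 (E = 2.5)
#' @export
chiSquaredUniformity <- function(cg, alpha = 0.05,
                                 variant = c("pearson", "as_printed")) {
  variant <- match.arg(variant)
  O <- if (methods::is(cg, "Correlogram")) counts(cg) else as.numeric(cg)
  L <- length(O)
  if (L < 2L) stop("need at least 2 bins")
  S <- sum(O)
  if (S == 0) stop("empty correlogram: no events to test")
  E <- S / L
  dev2 <- (O - E)^2
  chi2 <- if (variant == "pearson") sum(dev2) / E else sum(dev2)
  p <- stats::pchisq(chi2, df = L - 1L, lower.tail = FALSE)
  list(chi2 = chi2, pValue = p, uniform = p > alpha,
       expectedCountWarning = E < 5)
}

# Tricube weights and local quadratic fit used by the smoother.
.loessCoef <- function(d, degree = 2L) {
  w <- (1 - (abs(d) / (max(abs(d)) + 1))^3)^3
  X <- stats::poly(d, degree = degree, raw = TRUE)
  X <- cbind(1, X)
  A <- crossprod(X, w * X)
  # row of the hat matrix for the evaluation point d = 0
  drop(solve(A, t(w * X))[1L, ])
}

#' Smooth a correlogram by local quadratic regression
#'
#' Loess-style smoother: at each bin a weighted (tricube) quadratic is fit
#' over a centered window of W bins and evaluated at the bin itself. At the
#' edges the window is truncated to the available bins (with the fit degree
#' reduced when fewer than three bins remain). W = 1 returns the input
#' unchanged. Exactly quadratic inputs are reproduced to numerical
#' precision.
#'
#' @param x numeric vector (per-bin probabilities).
#' @param W odd window size in bins, \code{1 <= W <= length(x)}.
#' @return numeric vector of smoothed values, same length as \code{x}.
#' @export
smoothCorrelogram <- function(x, W) {
  L <- length(x)
  W <- as.integer(W)
  if (W %% 2L == 0L) stop("smoothing window W must be odd")
  if (W < 1L || W > L) stop("smoothing window W must be in [1, length(x)]")
  if (W == 1L) return(x)
  h <- (W - 1L) %/% 2L
  out <- numeric(L)
  # interior: one set of filter coefficients, applied as a convolution
  # (the coefficient vector is symmetric, so orientation is immaterial)
  cf <- .loessCoef(-h:h)
  filt <- stats::filter(x, cf, sides = 2)
  interior <- (h + 1L):(L - h)
  out[interior] <- as.numeric(filt[interior])
  # truncated edge windows
  for (i in c(seq_len(min(h, L)), if (L > h) (L - h + 1L):L)) {
    if (i >= h + 1L && i <= L - h) next
    win <- max(1L, i - h):min(L, i + h)
    d <- win - i
    deg <- min(2L, length(win) - 1L)
    if (deg == 0L) { out[i] <- x[win]; next }
    out[i] <- sum(.loessCoef(d, degree = deg) * x[win])
  }
  out
}

#' Prominence-based peak detection
#'
#' A peak is a strict local maximum (plateaus collapse to their center
#' bin); the first and last bins cannot be peaks. The prominence of a peak
#' is its height minus the higher of its two reference minima, each
#' reference minimum being the lowest value between the peak and its
#' nearest strictly higher value on that side (or the signal end). Only
#' peaks whose prominence strictly exceeds \code{minProminence} are kept --
#' for correlograms the natural floor is 1/L, so only peaks that stand out
#' above uniform-level wiggles survive.
#'
#' @param x numeric vector with at least 3 elements (typically a smoothed
#'   correlogram).
#' @param minProminence strict prominence floor.
#' @return data.frame with columns \code{index}, \code{value},
#'   \code{prominence}, one row per retained peak, ordered by index.
#' @export
findPeaks <- function(x, minProminence = 0) {
  L <- length(x)
  if (L < 3L) stop("need at least 3 bins")
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  nRuns <- length(r$values)
  out <- list()
  for (j in seq_len(nRuns)) {
    a <- starts[j]; b <- ends[j]
    if (a == 1L || b == L) next                    # endpoints are not peaks
    v <- r$values[j]
    if (!(r$values[j - 1L] < v && r$values[j + 1L] < v)) next
    p <- a + (b - a) %/% 2L                        # plateau center
    # walk left until a strictly higher value (or the start)
    leftMin <- Inf
    i <- a - 1L
    while (i >= 1L && x[i] <= v) { leftMin <- min(leftMin, x[i]); i <- i - 1L }
    rightMin <- Inf
    i <- b + 1L
    while (i <= L && x[i] <= v) { rightMin <- min(rightMin, x[i]); i <- i + 1L }
    prom <- v - max(leftMin, rightMin)
    if (prom > minProminence)
      out[[length(out) + 1L]] <- c(p, v, prom)
  }
  if (!length(out))
    return(data.frame(index = integer(), value = numeric(),
                      prominence = numeric()))
  m <- do.call(rbind, out)
  data.frame(index = as.integer(m[, 1L]), value = m[, 2L],
             prominence = m[, 3L])
}

#' Count and locate correlogram peaks
#'
#' Smooths the normalized correlogram with [smoothCorrelogram()] and
#' detects peaks with [findPeaks()]; peak times are the bin-center lags of
#' the detected peaks, in seconds relative to lag 0.
#'
#' @param cg a non-sparse \linkS4class{Correlogram}.
#' @param params a [metricParams()] list.
#' @return list with \code{peakCount} and \code{peakTimes} (seconds).
#' @export
countAndTimePeaks <- function(cg, params = metricParams()) {
  p <- probs(cg)
  if (anyNA(p)) stop("empty correlogram: no events")
  L <- length(p)
  sm <- smoothCorrelogram(p, params$smoothWindow)
  floorProm <- params$minProminence %||% (1 / L)
  pk <- findPeaks(sm, minProminence = floorProm)
  list(peakCount = nrow(pk), peakTimes = binCenters(cg)[pk$index])
}

#' Area left of zero
#'
#' The fraction of correlogram probability mass at negative lags,
#' \code{A = sum_{x<0} C(x)}, quantifying how consistently the comparison
#' signal fires before the reference: A = 1 means the comparison always
#' leads, A = 0 always follows, A = 0.5 no consistent order. Half of the
#' center-bin mass is included by default so that swapping the roles of the
#' two signals gives exactly \code{A' = 1 - A} even when mass sits at lag
#' 0; \code{centerBin = "exclude"} drops the center bin instead.
#'
#' @param cg a non-sparse \linkS4class{Correlogram}.
#' @param centerBin \code{"split"} or \code{"exclude"}.
#' @return A in \code{[0, 1]}, or \code{NA} for an empty correlogram.
#' @export
areaLeftOfZero <- function(cg, centerBin = c("split", "exclude")) {
  centerBin <- match.arg(centerBin)
  p <- probs(cg)
  if (anyNA(p)) return(NA_real_)
  ctr <- (length(p) + 1L) %/% 2L
  A <- sum(p[seq_len(ctr - 1L)])
  if (centerBin == "split") A <- A + p[ctr] / 2
  A
}

#' Shape metrics for every correlogram in a set
#'
#' Computes the chi-squared uniformity test, peak count and peak times, and
#' area left of zero for every non-sparse correlogram of a
#' \linkS4class{CorrelogramSet}. Sparse correlograms are retained as rows
#' with missing metrics and \code{sparse = TRUE}.
#'
#' @param cset a \linkS4class{CorrelogramSet}.
#' @param params a [metricParams()] list.
#' @return data.frame with one row per (region, refId, cmpId): event
#'   bookkeeping, \code{chi2}, \code{p_value}, \code{uniform},
#'   \code{expected_count_warning}, \code{peak_count}, \code{peak_times}
#'   (semicolon-joined seconds), \code{area_left}, \code{sparse}.
#' @export
shapeMetrics <- function(cset, params = metricParams()) {
  cd <- colData(cset)
  cnts <- assay(cset, "counts")
  centers <- rowData(cset)$binCenter
  L <- nrow(cnts)
  ctr <- (L + 1L) %/% 2L
  floorProm <- params$minProminence %||% (1 / L)
  n <- ncol(cnts)
  chi2 <- pval <- area <- rep(NA_real_, n)
  unif <- ewarn <- rep(NA, n)
  pkc <- rep(NA_integer_, n)
  pkt <- rep(NA_character_, n)
  neg <- seq_len(ctr - 1L)
  for (j in seq_len(n)) {
    if (cd$sparse[j]) next
    O <- cnts[, j]
    S <- sum(O)
    E <- S / L
    dev2 <- sum((O - E)^2)
    chi2[j] <- if (params$chi2Variant == "pearson") dev2 / E else dev2
    pval[j] <- stats::pchisq(chi2[j], df = L - 1L, lower.tail = FALSE)
    unif[j] <- pval[j] > params$alpha
    ewarn[j] <- E < 5
    p <- O / S
    sm <- smoothCorrelogram(p, params$smoothWindow)
    pk <- findPeaks(sm, minProminence = floorProm)
    pkc[j] <- nrow(pk)
    pkt[j] <- paste(centers[pk$index], collapse = ";")
    A <- sum(p[neg])
    if (params$centerBin == "split") A <- A + p[ctr] / 2
    area[j] <- A
  }
  data.frame(region = cd$regionIndex, ref_id = cd$refId, cmp_id = cd$cmpId,
             n_ref = cd$nRef, n_cmp = cd$nCmp, n_pairs = cd$nPairs,
             total = cd$total, sparse = cd$sparse,
             chi2 = chi2, p_value = pval, uniform = unif,
             expected_count_warning = ewarn,
             peak_count = pkc, peak_times = pkt, area_left = area,
             row.names = NULL)
}
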