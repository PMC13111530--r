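# Independent oracles used across the suite. These deliberately use naive
# algorithms (all-pairs double loops, explicit nearest-center searches) so
# they share no code path with the implementation they check.

# Nearest-center bin assignment by exhaustive search over candidate centers;
# exact half-edge ties resolved toward zero by preferring the smaller |k|.
oracleAssignBin <- function(lag, w, K) {
  ks <- -K:K
  d <- abs(lag - ks * w)
  cand <- ks[d <= min(d) + 1e-15]
  cand[which.min(abs(cand))]
}

# Brute-force all-pairs correlogram: every (t_r, t_c) pair with |lag| <= R.
oracleCorrelogram <- function(refT, cmpT, R, w, auto = FALSE) {
  K <- round(R / w)
  counts <- integer(2 * K + 1)
  for (i in seq_along(refT)) {
    for (j in seq_along(cmpT)) {
      if (auto && i == j) next
      lag <- cmpT[j] - refT[i]
      if (abs(lag) > R) next
      k <- oracleAssignBin(lag, w, K)
      counts[k + K + 1] <- counts[k + K + 1] + 1L
    }
  }
  counts
}

# Prominence of every strict local maximum, straight from the definition.
oraclePeaks <- function(x, minProm) {
  L <- length(x)
  out <- data.frame(index = integer(), prominence = numeric())
  for (i in 2:(L - 1)) {
    if (!(x[i] > x[i - 1] && x[i] > x[i + 1])) next
    left <- x[seq_len(i - 1)]
    higherL <- which(left > x[i])
    leftMin <- min(left[seq(if (length(higherL)) max(higherL) + 1 else 1,
                            i - 1)])
    right <- x[(i + 1):L]
    higherR <- which(right > x[i])
    rightMin <- min(right[seq_len(if (length(higherR)) min(higherR) - 1
                                  else length(right))])
    prom <- x[i] - max(leftMin, rightMin)
    if (prom > minProm)
      out <- rbind(out, data.frame(index = i, prominence = prom))
  }
  out
}

randomTrain <- function(n, tmax) sort(runif(n, 0, tmax))

tinyRecording <- function() {
  SpikeRecording(list(a = c(0.1, 0.2, 0.3), b = c(0.15, 0.25, 0.35)),
                 duration = 1)
}
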