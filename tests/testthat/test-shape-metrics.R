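mkcg <- function(counts, w = 0.01) {
  L <- length(counts)
  K <- (L - 1L) %/% 2L
  new("Correlogram", refId = "a", cmpId = "b", regionIndex = 1L,
      binCenters = (-K:K) * w, counts = as.integer(counts),
      nRef = max(1L, as.integer(sum(counts))),
      nCmp = max(1L, as.integer(sum(counts))),
      binWidth = w, range = K * w)
}

test_that("chi-squared uniformity matches hand computation and the stats oracle", {
  r <- chiSquaredUniformity(c(5, 5, 5, 5))
  expect_equal(r$chi2, 0)
  expect_equal(r$pValue, 1)
  expect_true(r$uniform)

  r2 <- chiSquaredUniformity(c(10, 0, 0, 0))
  expect_equal(r2$chi2, 30)  # E = 2.5, sum((O-E)^2/E)
  expect_equal(r2$pValue, pchisq(30, 3, lower.tail = FALSE))
  expect_false(r2$uniform)
  expect_true(r2$expectedCountWarning)

  # independent oracle: stats::chisq.test on random counts
  set.seed(13)
  for (i in 1:10) {
    O <- rpois(21, 8) + 1L
    mine <- chiSquaredUniformity(O)
    ref <- suppressWarnings(stats::chisq.test(O))
    expect_equal(mine$chi2, unname(ref$statistic))
    expect_equal(mine$pValue, unname(ref$p.value))
  }
})

test_that("a p-value exactly at the cutoff classifies as nonuniform", {
  O <- c(10, 0, 0, 0)
  p <- chiSquaredUniformity(O)$pValue
  expect_false(chiSquaredUniformity(O, alpha = p)$uniform)
  expect_equal(as.character(classifyUniformity(0.05, 0.05)), "nonuniform")
})

test_that("the literal printed statistic is the Pearson one scaled by E", {
  O <- c(7, 3, 9, 1, 5)
  E <- sum(O) / length(O)
  expect_equal(chiSquaredUniformity(O, variant = "as_printed")$chi2,
               chiSquaredUniformity(O, variant = "pearson")$chi2 * E)
})

test_that("chi-squared is permutation-invariant and respects concentration", {
  set.seed(17)
  O <- rpois(31, 6)
  base <- chiSquaredUniformity(O)$chi2
  for (i in 1:5)
    expect_equal(chiSquaredUniformity(sample(O))$chi2, base)
  # moving one event from the emptiest to the fullest bin concentrates mass
  for (i in 1:20) {
    O2 <- rpois(15, 5) + 1L
    lo <- which.min(O2); hi <- which.max(O2)
    O3 <- O2; O3[lo] <- O3[lo] - 1L; O3[hi] <- O3[hi] + 1L
    expect_gte(chiSquaredUniformity(O3)$chi2, chiSquaredUniformity(O2)$chi2)
  }
})

test_that("local quadratic smoothing reproduces quadratics and constants", {
  k <- seq_len(101)
  q <- 0.5 + 0.02 * k - 1e-4 * k^2
  for (W in c(5, 11, 25)) {
    expect_equal(smoothCorrelogram(q, W), q, tolerance = 1e-9)
  }
  expect_identical(smoothCorrelogram(q, 1), q)
  cst <- rep(1 / 101, 101)
  expect_equal(smoothCorrelogram(cst, 15), cst, tolerance = 1e-12)
  expect_error(smoothCorrelogram(q, 4), "odd")
  expect_error(smoothCorrelogram(q, 103), "W")
})

test_that("smoothing actually attenuates high-frequency noise", {
  set.seed(19)
  x <- rep(0.01, 201) + rnorm(201, 0, 0.002)
  sm <- smoothCorrelogram(x, 21)
  expect_lt(sd(sm[30:170]), sd(x[30:170]) / 2)
})

test_that("peak detection matches the brute-force prominence oracle", {
  expect_equal(nrow(findPeaks(rep(0.2, 10))), 0L)

  L <- 2001
  x <- rep(0, L); x[700] <- 1
  pk <- findPeaks(x, minProminence = 1 / L)
  expect_equal(pk$index, 700L)
  expect_equal(pk$prominence, 1)

  # three isolated bumps over a flat baseline, L = 101
  y <- rep(1 / 101, 101)
  y[c(20, 50, 80)] <- y[c(20, 50, 80)] + 3 / 101
  pk3 <- findPeaks(y, minProminence = 1 / 101)
  expect_equal(pk3$index, c(20L, 50L, 80L))
  expect_equal(pk3[, c("index", "prominence")],
               oraclePeaks(y, 1 / 101), ignore_attr = TRUE,
               tolerance = 1e-12)

  set.seed(23)
  for (i in 1:20) {
    z <- abs(rnorm(60))
    mine <- findPeaks(z, minProminence = 0.1)
    ref <- oraclePeaks(z, 0.1)
    expect_equal(mine$index, ref$index)
    expect_equal(mine$prominence, ref$prominence, tolerance = 1e-12)
  }
})

test_that("plateaus collapse to their center and endpoints are never peaks", {
  x <- c(0, 1, 1, 1, 0, 2, 0)
  pk <- findPeaks(x)
  expect_equal(pk$index, c(3L, 6L))
  expect_equal(nrow(findPeaks(c(5, 1, 1, 1, 4))), 0L)  # only boundary maxima
})

test_that("mirroring the input mirrors peak times and preserves the count", {
  set.seed(29)
  x <- abs(rnorm(81)) + 0.1
  pk <- findPeaks(x, minProminence = 0.05)
  pkr <- findPeaks(rev(x), minProminence = 0.05)
  expect_equal(rev(82L - pk$index), pkr$index)
  expect_equal(nrow(pk), nrow(pkr))
})

test_that("peak counting composes smoothing and detection on correlograms", {
  unif <- mkcg(rep(5L, 101))
  expect_equal(countAndTimePeaks(unif)$peakCount, 0L)

  d <- rep(0L, 2001); d[1001 + 10] <- 50L  # delta at +10 ms, 1 ms bins
  delta <- mkcg(d, w = 0.001)
  pk <- countAndTimePeaks(delta)
  expect_equal(pk$peakCount, 1L)
  expect_equal(pk$peakTimes, 0.010)

  # periodic bumps at 0, +/-0.25, +/-0.5, +/-0.75 s within +/-1 s (5 ms bins)
  ctr <- (-200:200) * 0.005
  z <- rep(1L, 401)
  bump <- round(30 * exp(-((-8:8) / 3)^2))
  for (c0 in c(-0.75, -0.5, -0.25, 0, 0.25, 0.5, 0.75)) {
    i <- which.min(abs(ctr - c0))
    z[(i - 8):(i + 8)] <- z[(i - 8):(i + 8)] + bump
  }
  per <- mkcg(z, w = 0.005)
  pk7 <- countAndTimePeaks(per, metricParams(smoothWindow = 5))
  expect_equal(pk7$peakCount, 7L)
  expect_equal(pk7$peakTimes, c(-0.75, -0.5, -0.25, 0, 0.25, 0.5, 0.75))
})

test_that("area left of zero follows the half-center-bin rule", {
  cg <- mkcg(c(20L, 30L, 10L, 25L, 15L))
  expect_equal(areaLeftOfZero(cg), 0.55)             # 0.2 + 0.3 + 0.05
  expect_equal(areaLeftOfZero(cg, "exclude"), 0.5)   # 0.2 + 0.3
  sym <- mkcg(c(3L, 7L, 11L, 7L, 3L))
  expect_equal(areaLeftOfZero(sym), 0.5)
  expect_true(is.na(areaLeftOfZero(mkcg(rep(0L, 5)))))
})

test_that("complementarity A_ij + A_ji = 1 holds exactly for mirrored pairs", {
  set.seed(37)
  spec <- correlogramSpec(0.1, 0.01)
  for (i in 1:25) {
    a <- randomTrain(sample(3:40, 1), 1)
    b <- randomTrain(sample(3:40, 1), 1)
    ab <- buildCorrelogram(a, b, spec, refId = "a", cmpId = "b")
    ba <- buildCorrelogram(b, a, spec, refId = "b", cmpId = "a")
    if (totalEvents(ab) == 0) next
    expect_equal(areaLeftOfZero(ab) + areaLeftOfZero(ba), 1,
                 tolerance = 1e-12)
  }
})

test_that("shapeMetrics flags sparse pairs and reports the rest", {
  rec <- SpikeRecording(list(a = randomTrain(40, 10), b = randomTrain(30, 10),
                             c = numeric()), duration = 10)
  cs <- correlogramSet(rec, spec = correlogramSpec(0.1, 0.01))
  m <- shapeMetrics(cs)
  expect_equal(nrow(m), 9L)
  expect_true(all(is.na(m$chi2[m$sparse])))
  ok <- m[!m$sparse, ]
  expect_true(all(ok$p_value >= 0 & ok$p_value <= 1))
  expect_true(all(ok$area_left >= 0 & ok$area_left <= 1))
  # the metrics table agrees with per-correlogram computation
  cg <- correlogram(cs, "a", "b")
  row <- m[m$ref_id == "a" & m$cmp_id == "b", ]
  expect_equal(row$chi2, chiSquaredUniformity(cg)$chi2)
  expect_equal(row$area_left, areaLeftOfZero(cg))
})
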