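test_that("bin geometry is odd with the center bin at lag zero", {
  b <- makeBins(correlogramSpec(1, 0.001))
  expect_equal(b$nBins, 2001L)
  expect_equal(b$centers[1001], 0)
  expect_equal(range(b$centers), c(-1, 1))
  expect_equal(makeBins(correlogramSpec(0.005, 0.001))$nBins, 11L)
  expect_error(correlogramSpec(1, 2), "fewer than 3 bins")
  expect_error(correlogramSpec(1, 3), "twice the range")
})

test_that("bin assignment is nearest-center with half-edge ties toward zero", {
  expect_equal(assignBin(0.0025, 0.001), 2L)
  expect_equal(assignBin(-0.0065, 0.001), -6L)
  expect_equal(assignBin(0, 0.001), 0L)
  expect_equal(assignBin(c(0.0024, 0.0026), 0.001), c(2L, 3L))
  expect_equal(assignBin(c(0.0015, -0.0015), 0.001), c(1L, -1L))
  # beyond range + half a bin: excluded
  expect_true(is.na(assignBin(0.12, 0.001, range = 0.1)))
  expect_equal(assignBin(0.1004, 0.001, range = 0.1), 100L)
})

test_that("bin assignment agrees with exhaustive nearest-center search", {
  set.seed(31)
  w <- 0.001; K <- 100L
  lags <- c(runif(300, -0.1, 0.1),
            (sample(-100:99, 50) + 0.5) * w)  # exact half-edges
  mine <- assignBin(lags, w)
  ref <- vapply(lags, oracleAssignBin, integer(1L), w = w, K = K)
  expect_identical(mine, ref)
})

test_that("the worked pair example produces the enumerated bins", {
  spec <- correlogramSpec(1, 0.001)
  cg <- buildCorrelogram(c(0, 0.5), c(0.1, 0.6, 2.0), spec,
                         refId = "a", cmpId = "b")
  expect_equal(totalEvents(cg), 4L)
  occ <- counts(cg) > 0
  expect_equal(binCenters(cg)[occ], c(-0.4, 0.1, 0.6))
  expect_equal(counts(cg)[occ], c(1L, 2L, 1L))
  expect_equal(sum(probs(cg)), 1)
})

test_that("autocorrelograms exclude self-pairs; coincident cross events count", {
  spec <- correlogramSpec(0.05, 0.005)
  auto <- buildCorrelogram(0.0, 0.0, spec, refId = "a", cmpId = "a")
  expect_equal(totalEvents(auto), 0L)
  expect_true(isSparse(auto))

  cross <- buildCorrelogram(0.0, 0.0, spec, refId = "a", cmpId = "b")
  expect_equal(probs(cross)[(nBins(cross) + 1L) %/% 2L], 1)  # center bin
  expect_equal(totalEvents(cross), 1L)
})

test_that("builder counts equal the brute-force all-pairs histogram", {
  set.seed(41)
  spec <- correlogramSpec(0.1, 0.01)
  for (i in 1:30) {
    n1 <- sample(0:120, 1); n2 <- sample(0:120, 1)
    a <- randomTrain(n1, 2); b <- randomTrain(n2, 2)
    cg <- buildCorrelogram(a, b, spec, refId = "a", cmpId = "b")
    expect_identical(counts(cg), oracleCorrelogram(a, b, 0.1, 0.01))
  }
  # autocorrelogram path (self-pairs excluded, duplicates retained)
  a <- sort(c(randomTrain(60, 2), 0.5, 0.5))
  cg <- buildCorrelogram(a, a, spec, refId = "a", cmpId = "a")
  expect_identical(counts(cg), oracleCorrelogram(a, a, 0.1, 0.01, auto = TRUE))
})

test_that("mirror symmetry: counts of (i,j) reversed equal counts of (j,i)", {
  set.seed(43)
  spec <- correlogramSpec(0.1, 0.005)
  for (i in 1:10) {
    a <- randomTrain(80, 3); b <- randomTrain(60, 3)
    ab <- buildCorrelogram(a, b, spec, refId = "a", cmpId = "b")
    ba <- buildCorrelogram(b, a, spec, refId = "b", cmpId = "a")
    expect_identical(rev(counts(ab)), counts(ba))
  }
})

test_that("counts are invariant under joint time translation", {
  set.seed(47)
  spec <- correlogramSpec(0.1, 0.005)
  a <- randomTrain(70, 5); b <- randomTrain(50, 5)
  reg0 <- data.frame(index = 1, start = 0, end = 5)
  reg1 <- data.frame(index = 1, start = 123.4, end = 128.4)
  cg0 <- buildCorrelogram(a, b, spec, region = reg0, refId = "a", cmpId = "b")
  cg1 <- buildCorrelogram(a + 123.4, b + 123.4, spec, region = reg1,
                          refId = "a", cmpId = "b")
  expect_identical(counts(cg0), counts(cg1))
  expect_true(sum(counts(cg0)) <= length(a) * length(b))
})

test_that("region filtering keeps each region self-contained", {
  spec <- correlogramSpec(0.5, 0.05)
  a <- c(0.9, 1.1); b <- c(1.05, 0.95)
  reg <- data.frame(index = 1, start = 1.0, end = 2.0)
  cg <- buildCorrelogram(a, b, spec, region = reg, refId = "a", cmpId = "b")
  # only the events >= 1.0 pair up: ref 1.1 with cmp 1.05
  expect_equal(totalEvents(cg), 1L)
  expect_equal(cg@nRef, 1L)
  expect_equal(cg@nCmp, 1L)
})

test_that("correlogram sets cover all N^2 pairs and keep silent units", {
  rec <- SpikeRecording(list(a = c(0.1, 0.5), b = c(0.2, 0.6),
                             c = numeric()), duration = 1)
  spec <- correlogramSpec(0.05, 0.005)
  cs <- correlogramSet(rec, spec = spec)
  expect_s4_class(cs, "CorrelogramSet")
  expect_equal(ncol(cs), 9L)
  cd <- SummarizedExperiment::colData(cs)
  expect_true(all(cd$sparse[cd$refId == "c" | cd$cmpId == "c"]))

  sub <- correlogramSet(rec, spec = correlogramSpec(0.05, 0.005,
                                                    referenceSubset = "a"))
  expect_equal(ncol(sub), 3L)

  # mirror check through the set extractor
  ab <- correlogram(cs, "a", "b")
  ba <- correlogram(cs, "b", "a")
  expect_identical(rev(counts(ab)), counts(ba))
})

test_that("sparsity flags follow the raster-event-product threshold", {
  cg <- buildCorrelogram(randomTrain(5, 1), randomTrain(10, 1),
                         correlogramSpec(0.5, 0.05), refId = "a", cmpId = "b")
  expect_false(isSparse(cg, 0))          # has events, threshold 0
  expect_true(isSparse(cg, 100))         # 5*10 = 50 <= 100
  empty <- buildCorrelogram(numeric(), numeric(),
                            correlogramSpec(0.5, 0.05),
                            refId = "a", cmpId = "b")
  expect_true(isSparse(empty, 0))        # empty is always sparse
})
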