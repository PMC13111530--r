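test_that("uniformity classification treats the cutoff as nonuniform", {
  expect_equal(as.character(classifyUniformity(c(0.5, 0.05, 0))),
               c("uniform", "nonuniform", "nonuniform"))
})

test_that("peak-count classes cap at the user ceiling", {
  expect_equal(as.character(classifyPeakCount(3, 4)), "3")
  expect_equal(as.character(classifyPeakCount(12, 10)), "10+")
  expect_equal(levels(classifyPeakCount(0, 4)), c("0", "1", "2", "3", "4+"))
  expect_equal(nlevels(classifyPeakCount(0, 10)), 11L)
})

test_that("timescale classes are log decades anchored at the range", {
  cls <- classifyPeakTimes(c(0, 0.0005, 0.0025, 0.05, 0.5, 1),
                           "timescale", range = 1)
  expect_equal(nlevels(cls), 4L)
  expect_equal(as.integer(cls), c(1L, 1L, 2L, 3L, 4L, 4L))
  expect_error(classifyPeakTimes(1.5, "timescale", range = 1), "within")
})

test_that("frequency bands are contiguous and zero lags are excluded", {
  # |t| = 0.2 s -> 5 Hz -> theta
  expect_equal(as.character(classifyPeakTimes(0.2, "frequency", range = 1)),
               "theta")
  f <- classifyPeakTimes(1 / c(2, 4, 7.5, 8, 12.5, 13, 31, 32, 100),
                         "frequency", range = 1)
  expect_equal(as.character(f),
               c("delta", "theta", "theta", "alpha", "alpha",
                 "beta", "beta", "gamma", "gamma"))
  expect_length(classifyPeakTimes(0, "frequency", range = 1), 0L)
  # a zero lag belongs to the smallest timescale class instead
  expect_equal(as.integer(classifyPeakTimes(0, "timescale", range = 1)), 1L)
})

test_that("leader/follower intervals partition [0,1] per the boundary audit", {
  A <- c(0, 0.1, 0.15, 0.2, 0.25, 0.3, 0.35, 0.4, 0.5, 0.6,
         0.7, 0.8, 0.85, 0.9, 1)
  expected <- c("strong", "strong", "fairly_strong", "fairly_strong",
                "intermediate", "intermediate", "fairly_weak", "fairly_weak",
                "weak", "fairly_weak", "intermediate", "fairly_strong",
                "fairly_strong", "strong", "strong")
  expect_equal(as.character(classifyLeaderFollower(A)), expected)
  expect_error(classifyLeaderFollower(1.2), "\\[0, 1\\]")
  # every value maps to exactly one class
  expect_false(anyNA(classifyLeaderFollower(seq(0, 1, by = 0.001))))
  # mirror consistency: A and 1 - A always share a class
  set.seed(51)
  A2 <- runif(200)
  expect_equal(classifyLeaderFollower(A2), classifyLeaderFollower(1 - A2))
})

mkrecords <- function() {
  # two units -> 2 cross correlograms per region, 3 regions
  grid <- expand.grid(region = 1:3,
                      pair = c("a|b", "b|a"), stringsAsFactors = FALSE)
  df <- data.frame(region = grid$region,
                   ref_id = sub("\\|.*", "", grid$pair),
                   cmp_id = sub(".*\\|", "", grid$pair),
                   sparse = FALSE,
                   p_value = c(0.5, 0.5, 0.01, 0.5, 0.5, 0.01),
                   peak_count = c(0L, 1L, 1L, 0L, 1L, 1L),
                   peak_times = c("", "0.25", "0.25", "", "-0.25", "-0.25"),
                   area_left = c(0.85, 0.5, 0.3, 0.15, 0.5, 0.7))
  classifyCorrelograms(df, maxPeaks = 4, range = 1)
}

test_that("mirror records share uniformity, peak and strength classes", {
  rr <- mkrecords()
  ab <- rr[rr$ref_id == "a", ]; ba <- rr[rr$ref_id == "b", ]
  expect_equal(ab$uniformity_class, ba$uniformity_class)
  expect_equal(ab$peak_class, ba$peak_class)
  expect_equal(ab$lf_class, ba$lf_class)
})

test_that("class fractions are normalized over non-sparse cross pairs", {
  rr <- mkrecords()
  fr <- classFractions(rr, "uniformity")
  byregion <- tapply(fr$fraction, fr$region, sum)
  expect_equal(as.numeric(byregion), c(1, 1, 1))
  expect_equal(fr$fraction[fr$region == 3 & fr$class == "nonuniform"], 1)

  df <- data.frame(region = 1, ref_id = c("a", "a", "b", "c"),
                   cmp_id = c("b", "c", "c", "d"), sparse = FALSE,
                   p_value = c(0.5, 0.01, 0.01, 0.01), peak_count = 0L,
                   peak_times = "", area_left = c(0.5, 0.5, 0.05, 0.95))
  rr2 <- classifyCorrelograms(df)
  fr2 <- classFractions(rr2, "uniformity")
  expect_equal(fr2$fraction[fr2$class == "uniform"], 0.25)
  fl <- classFractions(rr2, "lf")
  expect_equal(fl$fraction[fl$class %in% c("weak", "strong")], c(0.5, 0.5))
  expect_equal(sum(fl$fraction), 1)
})

test_that("transition tallies follow the toy sequence and stay row-stochastic", {
  # one correlogram: uniform, uniform, nonuniform across 3 regions
  df <- data.frame(region = 1:3, ref_id = "a", cmp_id = "b", sparse = FALSE,
                   p_value = c(0.5, 0.5, 0.01), peak_count = 0L,
                   peak_times = "", area_left = 0.5)
  rr <- classifyCorrelograms(df)
  tp <- transitionProbabilities(rr, "uniformity", step = "period",
                                periods = data.frame(index = 1:3,
                                                     period = factor("all")))
  uu <- tp$probability[tp$from_class == "uniform" & tp$to_class == "uniform"]
  un <- tp$probability[tp$from_class == "uniform" &
                       tp$to_class == "nonuniform"]
  expect_equal(uu, 0.5)
  expect_equal(un, 0.5)
  expect_equal(tp$support[tp$from_class == "uniform"], c(2, 2))

  # constant classifications give identity rows
  df2 <- do.call(rbind, lapply(1:5, function(r)
    data.frame(region = r, ref_id = c("a", "b"), cmp_id = c("b", "a"),
               sparse = FALSE, p_value = 0.5, peak_count = 1L,
               peak_times = "0.1", area_left = 0.5)))
  rr2 <- classifyCorrelograms(df2)
  tp2 <- transitionProbabilities(rr2, "uniformity", step = "region")
  obs <- tp2[tp2$support > 0, ]
  expect_true(all(obs$probability[obs$from_class == obs$to_class] == 1))
  rowsums <- tapply(tp2$probability[tp2$support > 0],
                    paste(tp2$grouping, tp2$from_class)[tp2$support > 0], sum)
  expect_true(all(abs(rowsums - 1) < 1e-12))
})

test_that("sparse endpoints are skipped and reported, not imputed", {
  df <- data.frame(region = rep(1:2, each = 2),
                   ref_id = c("a", "b", "a", "b"),
                   cmp_id = c("b", "a", "b", "a"),
                   sparse = c(FALSE, FALSE, TRUE, FALSE),
                   p_value = 0.5, peak_count = 0L, peak_times = "",
                   area_left = 0.5)
  rr <- classifyCorrelograms(df)
  tp <- transitionProbabilities(rr, "uniformity", step = "region")
  expect_equal(attr(tp, "skipped"), 1L)
  # a single surviving step: one tallied transition, from "uniform"
  expect_equal(unique(tp$support[tp$from_class == "uniform"]), 1)
  expect_equal(unique(tp$support[tp$from_class == "nonuniform"]), 0)
})

test_that("period pooling equals support-weighted pooling of region steps", {
  set.seed(53)
  df <- do.call(rbind, lapply(1:6, function(r)
    data.frame(region = r, ref_id = rep(letters[1:4], each = 4),
               cmp_id = rep(letters[1:4], 4),
               sparse = FALSE, p_value = runif(16), peak_count = 0L,
               peak_times = "", area_left = 0.5)))
  df <- df[df$ref_id != df$cmp_id, ]
  rr <- classifyCorrelograms(df)
  periods <- data.frame(index = 1:6,
                        period = factor(rep(c("before", "after"), each = 3),
                                        levels = c("before", "after")))
  byStep <- transitionProbabilities(rr, "uniformity", step = "region")
  byPeriod <- transitionProbabilities(rr, "uniformity", step = "period",
                                      periods = periods)
  stepReg <- as.integer(sub("to_region_", "", byStep$grouping))
  for (per in c("before", "after")) {
    stepsIn <- unique(stepReg[periods$period[stepReg] == per])
    for (fc in levels(rr$uniformity_class)) {
      sub <- byStep[stepReg %in% stepsIn & byStep$from_class == fc, ]
      flow <- ifelse(sub$support == 0, 0, sub$probability * sub$support)
      pooledCounts <- tapply(flow, sub$to_class, sum)
      want <- byPeriod[byPeriod$grouping == per & byPeriod$from_class == fc, ]
      tot <- sum(flow)
      if (tot == 0) next
      expect_equal(as.numeric(pooledCounts[as.character(want$to_class)] / tot),
                   want$probability, tolerance = 1e-12)
    }
  }
})

test_that("combined combos span the full grid and sum to 100 percent", {
  rr <- mkrecords()
  cc <- combinedComboTable(rr)
  expect_equal(nrow(cc), 2 * 5 * 5)  # maxPeaks = 4 -> 5 peak classes
  expect_equal(sum(cc$percent), 100, tolerance = 1e-9)
  expect_true(sum(cc$n > 0) <= nrow(rr))

  one <- classifyCorrelograms(
    data.frame(region = 1, ref_id = "a", cmp_id = "b", sparse = FALSE,
               p_value = 0.5, peak_count = 0L, peak_times = "",
               area_left = 0.5), maxPeaks = 10)
  cc1 <- combinedComboTable(one)
  expect_equal(nrow(cc1), 110L)
  expect_equal(cc1$percent[cc1$n == 1], 100)
})
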