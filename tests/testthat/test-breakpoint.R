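test_that("noiseless piecewise-linear cycles are recovered exactly", {
  cyc <- makeTwoSegCycle(knot = 720, slopeActive = 10, slopeResidual = 1)
  fit <- fitTwoSegment(cyc)
  expect_equal(knot(fit), 720, tolerance = 1e-6)
  expect_equal(fit@slopeActive, 10, tolerance = 1e-8)
  expect_equal(fit@slopeResidual, 1, tolerance = 1e-8)
  expect_lt(fit@sse, 1e-12)
  expect_false(fit@censored)
  expect_false(fit@degenerate)

  # knots off the sampling grid are found by the golden-section refinement
  cyc2 <- makeTwoSegCycle(knot = 713, by = 5)
  expect_equal(knot(fitTwoSegment(cyc2)), 713, tolerance = 1e-5)
})

test_that("a straight line is flagged degenerate", {
  t <- seq(0, 1440, by = 10)
  lin <- new("DailyCycle", cycleDay = 0L, tRel = t,
             ch4Rate = rep(NA_real_, length(t)), ch4Cumulative = 2 * t,
             incomplete = FALSE)
  fit <- fitTwoSegment(lin)
  expect_true(fit@degenerate)
})

test_that("inputs that cannot carry a two-segment fit are rejected", {
  short <- new("DailyCycle", cycleDay = 0L, tRel = c(0, 10, 20),
               ch4Rate = rep(NA_real_, 3), ch4Cumulative = c(0, 5, 9),
               incomplete = FALSE)
  expect_error(fitTwoSegment(short), "few samples")
  expect_error(fitTwoSegmentXY(seq(0, 100, 10), c(0, 2, 4, 3, 8, 10, 12, 14, 16, 18, 20)),
               "non-decreasing")
})

test_that("production fit matches the exhaustive grid oracle", {
  set.seed(77)
  for (i in 1:6) {
    trueKnot <- runif(1, 300, 1100)
    n <- sample(60:200, 1)
    t <- sort(runif(n, 0, 1440))
    y <- ifelse(t <= trueKnot, 8 * t, 8 * trueKnot + 0.8 * (t - trueKnot)) +
      rnorm(n, 0, 40)
    y <- cummax(y)
    fit <- fitTwoSegmentXY(t, y, refine = FALSE)
    orc <- oracleTwoSeg(t, y)
    expect_equal(knot(fit), orc$knot)
    expect_equal(fit@sse, orc$sse, tolerance = 1e-8)
    # refinement never worsens the SSE and two segments never beat one line
    fitR <- fitTwoSegmentXY(t, y, refine = TRUE)
    expect_lte(fitR@sse, fit@sse + 1e-9)
    expect_lte(fitR@sse, sum(resid(lm(y ~ t))^2) + 1e-9)
  }
})

test_that("noisy knots stay within two sampling intervals of the truth", {
  for (seed in 1:4) {
    cyc <- makeTwoSegCycle(knot = 840, slopeActive = 6, slopeResidual = 0.5,
                           by = 10, noiseSd = 25, seed = seed)
    fit <- fitTwoSegment(cyc)
    expect_lt(abs(knot(fit) - 840), 2 * 10 + 1e-9)
  }
})

test_that("delaying the true knot never decreases the estimate", {
  knots <- seq(500, 1100, by = 100)
  est <- vapply(knots, function(k) {
    cyc <- makeTwoSegCycle(knot = k, by = 10, noiseSd = 15, seed = 42)
    knot(fitTwoSegment(cyc))
  }, numeric(1))
  expect_true(all(diff(est) >= 0))
})

test_that("ties in SSE break towards the earliest knot", {
  # symmetric tent: the reversed curve has the mirrored SSE profile, so
  # both orientations must report the earlier of their tied knots
  t <- seq(0, 1440, by = 20)
  y <- cumsum(c(0, rep(1, 36), rep(1, 36)))  # straight line -> all knots tie
  fit <- fitTwoSegmentXY(t, y)
  expect_equal(knot(fit), t[4])  # first interior candidate
  expect_true(fit@degenerate)
})

test_that("breakpoint trend aggregates fits and measures drift", {
  cycles <- lapply(0:9, function(d)
    makeTwoSegCycle(knot = 720, day = d, by = 10))
  trend <- breakpointSeries(cycles)
  expect_equal(nrow(trend@entries), 10)
  expect_equal(trend@entries$knot, rep(720, 10), tolerance = 1e-6)
  expect_true(all(abs(trend@entries$driftSlope[-1]) < 1e-6))
  expect_true(is.na(detectDrift(trend)))

  drifting <- lapply(0:9, function(d)
    makeTwoSegCycle(knot = 720 + 40 * d, day = d, by = 10))
  trend2 <- breakpointSeries(drifting)
  expect_equal(trend2@entries$driftSlope[10], 40, tolerance = 1e-6)

  # incomplete cycles are excluded from trending
  cycles[[3]]@incomplete <- TRUE
  trend3 <- breakpointSeries(cycles)
  expect_equal(nrow(trend3@entries), 9)
  expect_false(2 %in% trend3@entries$day)

  # all-degenerate input gives an empty trend with a warning
  t <- seq(0, 1440, by = 20)
  lin <- lapply(0:2, function(d)
    new("DailyCycle", cycleDay = as.integer(d), tRel = t,
        ch4Rate = rep(NA_real_, length(t)), ch4Cumulative = 2 * t,
        incomplete = FALSE))
  expect_warning(trend4 <- breakpointSeries(lin), "degenerate")
  expect_equal(nrow(trend4@entries), 0)
})

test_that("drift alarm fires on sustained slope or level exceedance", {
  entries <- data.frame(day = 0:9, knot = c(rep(720, 5), 760, 820, 900, 1000, 1100),
                        censored = FALSE)
  entries$driftSlope <- c(NA, rep(0, 4), 8, 30, 55, 75, 88)
  trend <- new("BreakpointTrend", entries = entries, window = 7,
               alarmDay = NA_real_)
  # slope exceeds 15 from day 6 on; third consecutive day is day 8
  expect_equal(detectDrift(trend), 8)
  # a level exceedance fires immediately on the first exceeding day
  expect_equal(detectDrift(trend, levelThreshold = 950), 8)
  expect_equal(detectDrift(trend, levelThreshold = 850), 7)
  # flat trend never alarms
  flat <- new("BreakpointTrend",
              entries = data.frame(day = 0:9, knot = 720, censored = FALSE,
                                   driftSlope = c(NA, rep(0, 9))),
              window = 7, alarmDay = NA_real_)
  expect_true(is.na(detectDrift(flat)))
})

test_that("censored knots are reported at the window edge", {
  # knot beyond the candidate range: fit pins it at the edge and censors
  cyc <- makeTwoSegCycle(knot = 1435, by = 10)
  fit <- fitTwoSegment(cyc)
  expect_true(fit@censored)
  trend <- breakpointSeries(list(cyc))
  if (nrow(trend@entries)) expect_equal(trend@entries$knot, 1440)
})
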