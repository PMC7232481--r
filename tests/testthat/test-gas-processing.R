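test_that("volume normalisation matches the ideal-gas / Magnus computation", {
  # identity at normal conditions, zero maps to zero
  expect_equal(normalizeVolume(100, 0, 1013.25, FALSE), 100)
  expect_equal(normalizeVolume(0, 37, 990, TRUE), 0)

  # independent hand computation: p_w(37) = 6.1094 exp(17.625*37/280.04),
  # then flow * (p - p_w)/p0 * T0/TK
  pw <- 6.1094 * exp(17.625 * 37 / (37 + 243.04))
  expect_equal(pw, 62.71, tolerance = 1e-3)
  byHand <- 100 * (1013.25 - pw) / 1013.25 * 273.15 / 310.15
  expect_equal(normalizeVolume(100, 37, 1013.25, TRUE), byHand)
  expect_equal(byHand, 82.6, tolerance = 1e-3)

  # strictly decreasing in temperature at fixed pressure
  temps <- seq(5, 55, by = 5)
  out <- normalizeVolume(100, temps, 1013.25, FALSE)
  expect_true(all(diff(out) < 0))

  expect_error(normalizeVolume(10, -300, 1013.25), "temperature")
  expect_error(normalizeVolume(10, 20, -5), "pressure")
  # saturated stream at pressure below the vapour pressure is unphysical
  expect_error(normalizeVolume(10, 99, 900, TRUE), "saturation")
})

test_that("methane rate is the product of normalised flow and CH4 fraction", {
  gts <- gasTimeSeries(0:9, rep(10, 10), rep(0.5, 10))
  expect_equal(methaneRate(gts)$ch4Rate, rep(5, 10))

  gts0 <- gasTimeSeries(0:9, rep(10, 10), rep(0, 10))
  expect_equal(methaneRate(gts0)$ch4Rate, rep(0, 10))

  # 2600 mL/day at 55 % CH4 -> 1430 mL CH4/day, checked via the integral
  flow <- rep(2600 / 1440, 1441)
  gts2 <- gasTimeSeries(0:1440, flow, rep(0.55, 1441))
  r <- methaneRate(gts2)
  total <- sum(diff(r$time) * (r$ch4Rate[-1] + r$ch4Rate[-1441]) / 2)
  expect_equal(total, 1430, tolerance = 1e-6)
})

test_that("CH4 sensor alignment interpolates but refuses to extrapolate", {
  gts <- gasTimeSeries(0:10, rep(2, 11), rep(0, 11))
  al <- alignCh4(gts, c(0, 10), c(0.4, 0.6))
  expect_equal(al@ch4Fraction, seq(0.4, 0.6, length.out = 11))
  expect_error(alignCh4(gts, c(2, 10), c(0.4, 0.6)), "extrapolation")
})

test_that("running mean is exact on constants and truncated at edges", {
  expect_equal(runningMean(rep(3, 50), window = 15), rep(3, 50))

  # spec arithmetic example: middle of [0, 3, 0] with a 3-sample window
  out <- runningMean(c(0, 3, 0), time = 0:2, window = 2)
  expect_equal(out[2], 1)

  # truncated-window oracle on a step series
  x <- c(rep(0, 10), rep(6, 10))
  got <- runningMean(x, window = 5)
  want <- vapply(seq_along(x), function(i) {
    sel <- abs(seq_along(x) - i) <= 2.5
    mean(x[sel])
  }, numeric(1))
  expect_equal(got, want)

  # envelope: never outside the input min/max
  set.seed(3)
  y <- rnorm(200)
  sm <- runningMean(y, window = 21)
  expect_true(all(sm >= min(y) & sm <= max(y)))
  # interior (full-window) portion preserves the local mean structure:
  # the smoother is a linear filter with unit row sums
  expect_equal(mean(sm[50:150]), mean(sapply(50:150, function(i) mean(y[(i-10):(i+10)]))))

  expect_warning(runningMean(c(1, 2, 3), time = c(0, 10, 20), window = 5),
                 "sampling interval")
})

test_that("cycle segmentation partitions samples and integrates correctly", {
  t <- 0:(2 * 1440 - 1)
  gts <- gasTimeSeries(t, rep(1, length(t)), rep(1, length(t)))
  sched <- feedingSchedule(c(0, 1440))
  cyc <- segmentCycles(gts, sched)
  expect_length(cyc, 2)
  expect_equal(vapply(cyc, function(c) length(c@tRel), integer(1)),
               c(1440L, 1440L))
  # every in-span sample lands in exactly one cycle
  expect_equal(sum(vapply(cyc, function(c) length(c@tRel), integer(1))),
               length(t))
  # constant 1 mL/min integrates to t_rel at the cycle end
  expect_equal(max(cyc[[1]]@ch4Cumulative), max(cyc[[1]]@tRel))

  # pre-feed data are excluded from the first cycle
  sched2 <- feedingSchedule(c(100, 1540))
  cyc2 <- segmentCycles(gts, sched2)
  expect_equal(cyc2[[1]]@tRel[1], 0)
  expect_equal(length(cyc2[[1]]@tRel), 1440L)

  expect_error(segmentCycles(gts, feedingSchedule(c(0, 30))), "60 min")
  expect_error(segmentCycles(gts, feedingSchedule(4000 * 1440)), "span")

  # a >30 min gap marks the cycle incomplete
  keep <- !(t %in% 300:350)
  gts3 <- gasTimeSeries(t[keep], rep(1, sum(keep)), rep(1, sum(keep)))
  cyc3 <- segmentCycles(gts3, sched)
  expect_true(cyc3[[1]]@incomplete)
  expect_false(cyc3[[2]]@incomplete)
})

test_that("daily yield divides by OLR x volume and respects the Buswell cap", {
  sched <- feedingSchedule(0, reactorVolume = 4, hrt = 30, olr = 1.7)
  expect_equal(dailyYield(1430, sched), 1430 / 6.8)
  expect_equal(dailyYield(0, sched), 0)
  # full conversion of the fed COD reaches the stoichiometric maximum
  full <- 6.8 * codMethaneVolume()
  expect_equal(dailyYield(full, sched), codMethaneVolume())
})
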