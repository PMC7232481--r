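## Gas stream fusion, normalisation to dry normal conditions, smoothing and
## segmentation into feeding cycles.

#' Saturation vapour pressure of water (Magnus formula)
#'
#' \eqn{p_w = 6.1094 \exp(17.625 T / (T + 243.04))} hPa, accurate to better
#' than 1 percent over 0--60 degrees C.
#'
#' @param temperature degrees Celsius.
#' @return saturation vapour pressure, hPa.
#' @export
saturationVapourPressure <- function(temperature) {
  6.1094 * exp(17.625 * temperature / (temperature + 243.04))
}

#' Normalise a gas flow to dry normal conditions
#'
#' Ideal-gas rescaling of a volumetric flow measured at `temperature` and
#' `pressure` to dry normal conditions (0 degrees C, 1013.25 hPa). For a
#' water-saturated stream the water vapour partial pressure (Magnus formula)
#' is subtracted first:
#' \deqn{V_n = V \frac{p - p_w[sat]}{p_0} \frac{T_0}{T + T_0}}
#'
#' @param flow volumetric flow (any volume-per-time unit); returned in the
#'   same unit at dry normal conditions.
#' @param temperature gas temperature, degrees C.
#' @param pressure gas pressure, hPa.
#' @param waterSaturated logical; subtract water vapour partial pressure?
#' @return normalised flow, same length as `flow`.
#' @examples
#' normalizeVolume(100, 0, 1013.25, FALSE)        # identity
#' normalizeVolume(100, 37, 1013.25, TRUE)        # ~82.6
#' @export
normalizeVolume <- function(flow, temperature, pressure = 1013.25,
                            waterSaturated = FALSE) {
  n <- max(length(flow), length(temperature), length(pressure),
           length(waterSaturated))
  flow <- rep_len(flow, n); temperature <- rep_len(temperature, n)
  pressure <- rep_len(pressure, n); waterSaturated <- rep_len(waterSaturated, n)
  if (any(!is.finite(temperature)) || any(temperature <= -273.15))
    stop("non-physical 'temperature': must be finite and above -273.15 C")
  if (any(!is.finite(pressure)) || any(pressure <= 0))
    stop("non-physical 'pressure': must be finite and positive")
  pw <- ifelse(waterSaturated, saturationVapourPressure(temperature), 0)
  if (any(pressure <= pw))
    stop("'pressure' must exceed the water vapour saturation pressure for a saturated stream")
  flow * ((pressure - pw) / 1013.25) * (273.15 / (temperature + 273.15))
}

#' Align a methane fraction stream to a flow grid
#'
#' Linear interpolation of the CH4 sensor signal onto the gas-meter time
#' grid. Extrapolation outside the sensor's span is refused.
#'
#' @param gts a [GasTimeSeries-class] carrying the flow grid.
#' @param ch4Time sensor time stamps, minutes since start.
#' @param ch4Fraction sensor methane fraction in \eqn{[0,1]}.
#' @return a [GasTimeSeries-class] with the interpolated `ch4Fraction`.
#' @export
alignCh4 <- function(gts, ch4Time, ch4Fraction) {
  if (min(gts@time) < min(ch4Time) || max(gts@time) > max(ch4Time))
    stop("flow grid extends beyond the CH4 sensor span; extrapolation is not allowed")
  f <- stats::approx(ch4Time, ch4Fraction, xout = gts@time, rule = 1)$y
  initialize(gts, ch4Fraction = f)
}

#' Normalised methane production rate
#'
#' Element-wise product of the normalised flow and the methane fraction:
#' the minute-resolution methane production rate at dry normal conditions.
#'
#' @param series a [GasTimeSeries-class].
#' @return data.frame with columns `time` (min) and `ch4Rate`
#'   (mL CH4/min, dry normal).
#' @export
methaneRate <- function(series) {
  stopifnot(is(series, "GasTimeSeries"))
  if (!length(series)) stop("empty series")
  nflow <- normalizeVolume(series@flow, series@temperature, series@pressure,
                           series@waterSaturated)
  data.frame(time = series@time, ch4Rate = nflow * series@ch4Fraction)
}

#' Centred running mean over a time window
#'
#' Truncated centred moving average: the value at time t averages all
#' samples within \eqn{[t - w/2, t + w/2]}; at the edges the window is
#' truncated to the available samples. The output grid equals the input
#' grid. A window smaller than the sampling interval passes the series
#' through unchanged with a warning.
#'
#' @param x numeric series.
#' @param time sample times (minutes); defaults to a unit grid.
#' @param window window width in the units of `time` (default 15 min).
#' @return smoothed numeric series on the same grid.
#' @export
runningMean <- function(x, time = seq_along(x) - 1, window = 15) {
  stopifnot(window > 0, length(x) == length(time))
  n <- length(x)
  if (n < 2) return(x)
  if (window < min(diff(time))) {
    warning("window smaller than the sampling interval; returning the series unchanged")
    return(x)
  }
  cs <- c(0, cumsum(x))
  lo <- findInterval(time - window / 2, time, left.open = TRUE) + 1L
  hi <- findInterval(time + window / 2, time)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Segment a gas series into daily feeding cycles
#'
#' Cuts the normalised methane-rate stream at each feed event; each cycle
#' runs from its feed to the next one (capped at 1440 min). Cumulative
#' methane is integrated from the feed by the trapezoid rule. Cycles with an
#' internal sampling gap above `maxGap` minutes are flagged incomplete.
#'
#' @param series a [GasTimeSeries-class].
#' @param schedule a [FeedingSchedule-class]; at least one feed time must lie
#'   inside the series span, and feeds closer than 60 min are rejected.
#' @param maxGap largest tolerated sampling gap, minutes.
#' @param smoothWindow optional running-mean window (minutes) applied to the
#'   rate before segmentation (the display convention is 15 min).
#' @param sampleEvery optional thinning interval (minutes): keep roughly one
#'   sample per interval, shrinking dense minute-resolution streams before
#'   fitting.
#' @return list of [DailyCycle-class].
#' @export
segmentCycles <- function(series, schedule, maxGap = 30,
                          smoothWindow = NULL, sampleEvery = NULL) {
  stopifnot(is(series, "GasTimeSeries"), is(schedule, "FeedingSchedule"))
  feeds <- schedule@feedTimes
  if (any(diff(feeds) < 60))
    stop("overlapping feed events: feeds closer than 60 min apart")
  rate <- methaneRate(series)
  if (!is.null(smoothWindow))
    rate$ch4Rate <- runningMean(rate$ch4Rate, rate$time, smoothWindow)
  if (!is.null(sampleEvery)) {
    step <- max(1L, round(sampleEvery / stats::median(diff(rate$time))))
    rate <- rate[seq(1, nrow(rate), by = step), , drop = FALSE]
    maxGap <- max(maxGap, sampleEvery)
  }
  span <- range(rate$time)
  inSpan <- feeds >= span[1] & feeds < span[2]
  if (!any(inSpan)) stop("no feed time inside the series span")
  feeds <- feeds[inSpan]
  ends <- c(feeds[-1], Inf)
  cycles <- vector("list", length(feeds))
  for (i in seq_along(feeds)) {
    t0 <- feeds[i]
    t1 <- min(ends[i], t0 + 1440, span[2] + 1e-6)
    sel <- rate$time >= t0 & rate$time < t1
    tRel <- rate$time[sel] - t0
    r <- rate$ch4Rate[sel]
    cum <- if (length(tRel) > 1)
      c(0, cumsum(diff(tRel) * (r[-length(r)] + r[-1]) / 2)) else rep(0, length(tRel))
    incomplete <- length(tRel) < 2 ||
      max(diff(tRel)) > maxGap || tRel[1] > maxGap
    cycles[[i]] <- new("DailyCycle",
      cycleDay = as.integer(floor(t0 / 1440)), tRel = tRel, ch4Rate = r,
      ch4Cumulative = cum, incomplete = incomplete)
  }
  cycles
}

#' Methane yield per gram of COD fed
#'
#' @param dailyCh4 daily methane production, mL/day (dry normal).
#' @param schedule a [FeedingSchedule-class]; the denominator is
#'   OLR x reactor volume (gCOD fed per day).
#' @return mL CH4 per gCOD fed.
#' @examples
#' dailyYield(1430, feedingSchedule(0))  # ~210 mL/gCOD
#' @export
dailyYield <- function(dailyCh4, schedule) {
  stopifnot(is(schedule, "FeedingSchedule"))
  if (schedule@reactorVolume <= 0) stop("reactor volume must be positive")
  dailyCh4 / (schedule@olr * schedule@reactorVolume)
}
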