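## Two-segment piecewise regression of cumulative methane per feeding cycle,
## and day-by-day trending of the knot as an early-warning statistic.

# SSE and coefficients of the continuous two-piece model
#   y = b0 + b1 * t + b2 * max(t - c, 0)
# for a fixed knot c.
.twoSegFit <- function(t, y, c) {
  X <- cbind(1, t, pmax(t - c, 0))
  fit <- stats::lm.fit(X, y)
  list(coef = fit$coefficients, sse = sum(fit$residuals^2))
}

.singleLineSse <- function(t, y) {
  fit <- stats::lm.fit(cbind(1, t), y)
  sum(fit$residuals^2)
}

# Golden-section minimisation of SSE(c) on [lo, hi].
.goldenKnot <- function(t, y, lo, hi, tol = 1e-3) {
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  c1 <- b - phi * (b - a); c2 <- a + phi * (b - a)
  f1 <- .twoSegFit(t, y, c1)$sse; f2 <- .twoSegFit(t, y, c2)$sse
  while (b - a > tol) {
    if (f1 <= f2) {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - phi * (b - a); f1 <- .twoSegFit(t, y, c1)$sse
    } else {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + phi * (b - a); f2 <- .twoSegFit(t, y, c2)$sse
    }
  }
  if (f1 <= f2) c1 else c2
}

#' @describeIn fitTwoSegment Fit on a feeding cycle's cumulative methane.
#'
#' Minimises the total squared error of a continuous two-piece linear
#' function of cumulative CH4 versus time after feeding. Candidate knots are
#' the observed sample times excluding `edgeExclude` samples at each edge;
#' the best grid knot is then refined by golden-section search between its
#' neighbouring grid points. Ties in SSE are broken towards the earliest
#' knot (the conservative, earlier-alarm choice). The fit is `censored` when
#' the knot is pinned within one sampling interval of the candidate-window
#' edge and `degenerate` when the improvement over a single line is below
#' `degenerateTol` (no two-segment structure).
#'
#' @param edgeExclude number of samples excluded at each edge of the knot
#'   grid (default 3).
#' @param refine logical; golden-section refinement between grid neighbours.
#' @param degenerateTol relative SSE improvement below which the fit is
#'   declared degenerate (default 0.01).
#' @export
setMethod("fitTwoSegment", "DailyCycle",
  function(cycle, edgeExclude = 3L, refine = TRUE, degenerateTol = 0.01) {
    t <- cycle@tRel; y <- cycle@ch4Cumulative
    if (length(t) < 8) stop("too few samples in the cycle (need at least 8)")
    if (any(diff(y) < -1e-8 * max(abs(y), 1)))
      stop("cumulative CH4 must be non-decreasing")
    res <- .fitTwoSegmentCore(t, y, cycle@cycleDay, edgeExclude, refine,
                              degenerateTol)
    res
  })

# Shared core, also used by the numeric-vector convenience entry point.
.fitTwoSegmentCore <- function(t, y, cycleDay, edgeExclude, refine,
                               degenerateTol) {
  n <- length(t)
  idx <- (edgeExclude + 1L):(n - edgeExclude)
  if (length(idx) < 2) stop("too few interior samples for the knot grid")
  cand <- t[idx]
  sse1 <- .singleLineSse(t, y)

  sses <- vapply(cand, function(c) .twoSegFit(t, y, c)$sse, numeric(1))
  best <- which(sses <= min(sses) + 1e-12)[1]  # earliest among ties
  kn <- cand[best]
  sse <- sses[best]

  if (refine) {
    lo <- if (best > 1) cand[best - 1] else cand[best]
    hi <- if (best < length(cand)) cand[best + 1] else cand[best]
    if (hi > lo) {
      knR <- .goldenKnot(t, y, lo, hi)
      sseR <- .twoSegFit(t, y, knR)$sse
      if (sseR < sse - 1e-12) { kn <- knR; sse <- sseR }
    }
  }

  fit <- .twoSegFit(t, y, kn)
  b <- fit$coef
  interval <- stats::median(diff(t))
  censored <- kn >= cand[length(cand)] - interval + 1e-9 ||
              kn <= cand[1] + interval - 1e-9
  degenerate <- if (sse1 <= 1e-12) TRUE else (sse1 - sse) / sse1 < degenerateTol

  new("BreakpointFit",
    cycleDay = as.integer(cycleDay), knot = kn,
    slopeActive = unname(b[2]), slopeResidual = unname(b[2] + b[3]),
    intercept = unname(b[1]), sse = sse,
    censored = censored, degenerate = degenerate)
}

#' Two-segment fit of raw time/cumulative vectors
#'
#' Convenience wrapper over the [DailyCycle-class] method for data not
#' originating from [segmentCycles()].
#'
#' @param tRel minutes after feeding.
#' @param ch4Cumulative cumulative methane, mL.
#' @param cycleDay integer day label.
#' @param ... passed to the `DailyCycle` method.
#' @return a [BreakpointFit-class].
#' @export
fitTwoSegmentXY <- function(tRel, ch4Cumulative, cycleDay = 0L, ...) {
  cyc <- new("DailyCycle", cycleDay = as.integer(cycleDay), tRel = tRel,
             ch4Rate = rep(NA_real_, length(tRel)),
             ch4Cumulative = ch4Cumulative, incomplete = FALSE)
  fitTwoSegment(cyc, ...)
}

#' Day-by-day breakpoint trend
#'
#' Fits every complete cycle, drops degenerate fits, records censored knots
#' at 1440 min, and attaches the trailing-window drift slope (least-squares
#' slope of knot versus day over the `window` most recent days).
#'
#' @param cycles list of [DailyCycle-class] (incomplete ones are skipped).
#' @param window trailing window in days for the drift slope (default 7).
#' @param ... passed to [fitTwoSegment()].
#' @return a [BreakpointTrend-class] (with `alarmDay = NA`; see
#'   [detectDrift()]).
#' @export
breakpointSeries <- function(cycles, window = 7, ...) {
  cycles <- Filter(function(cy) !cy@incomplete && length(cy@tRel) >= 8, cycles)
  fits <- lapply(cycles, function(cy) {
    tryCatch(fitTwoSegment(cy, ...), error = function(e) NULL)
  })
  fits <- Filter(Negate(is.null), fits)
  fits <- Filter(function(f) !f@degenerate, fits)
  if (!length(fits)) {
    warning("all cycles degenerate or unusable; empty trend")
    entries <- data.frame(day = integer(), knot = numeric(),
                          censored = logical(), driftSlope = numeric())
    return(new("BreakpointTrend", entries = entries, window = window,
               alarmDay = NA_real_))
  }
  entries <- data.frame(
    day = vapply(fits, function(f) f@cycleDay, integer(1)),
    knot = vapply(fits, function(f) if (f@censored) 1440 else f@knot, numeric(1)),
    censored = vapply(fits, function(f) f@censored, logical(1))
  )
  entries <- entries[order(entries$day), ]
  entries <- entries[!duplicated(entries$day), ]
  rownames(entries) <- NULL
  entries$driftSlope <- vapply(seq_len(nrow(entries)), function(i) {
    sel <- entries$day > entries$day[i] - window & entries$day <= entries$day[i]
    if (sum(sel) < 2) return(NA_real_)
    stats::cov(entries$day[sel], entries$knot[sel]) / stats::var(entries$day[sel])
  }, numeric(1))
  new("BreakpointTrend", entries = entries, window = window, alarmDay = NA_real_)
}

#' Detect breakpoint drift (early-warning alarm)
#'
#' The alarm fires on the first day where either the trailing drift slope
#' exceeds `slopeThreshold` on at least three consecutive trend entries, or
#' the knot itself exceeds `levelThreshold`. Deterministic given its inputs;
#' returns `NA` when the criterion never holds.
#'
#' @param trend a [BreakpointTrend-class].
#' @param slopeThreshold min/day (default 15).
#' @param levelThreshold minutes (default 1200).
#' @return the alarm day (numeric) or `NA`.
#' @export
detectDrift <- function(trend, slopeThreshold = 15, levelThreshold = 1200) {
  e <- trend@entries
  if (!nrow(e)) return(NA_real_)
  slopeHit <- !is.na(e$driftSlope) & e$driftSlope > slopeThreshold
  runLen <- 0L
  for (i in seq_len(nrow(e))) {
    runLen <- if (slopeHit[i]) runLen + 1L else 0L
    if (runLen >= 3L) return(e$day[i])
    if (e$knot[i] > levelThreshold) return(e$day[i])
  }
  NA_real_
}

#' Attach the alarm state to a trend
#'
#' @param trend a [BreakpointTrend-class].
#' @param ... passed to [detectDrift()].
#' @return the trend with its `alarmDay` slot filled in.
#' @export
withAlarm <- function(trend, ...) {
  initialize(trend, alarmDay = detectDrift(trend, ...))
}
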