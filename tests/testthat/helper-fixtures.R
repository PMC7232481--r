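# Shared fixture builders; everything is generated in code at test time.

# A noiseless two-segment cumulative methane curve with a known knot.
makeTwoSegCycle <- function(knot = 720, slopeActive = 10, slopeResidual = 1,
                            by = 5, noiseSd = 0, seed = 1, day = 0L) {
  t <- seq(0, 1440, by = by)
  y <- ifelse(t <= knot, slopeActive * t,
              slopeActive * knot + slopeResidual * (t - knot))
  if (noiseSd > 0) {
    set.seed(seed)
    y <- y + rnorm(length(y), 0, noiseSd)
    y <- cummax(y)  # keep the cumulative curve non-decreasing
  }
  new("DailyCycle", cycleDay = as.integer(day), tRel = t,
      ch4Rate = rep(NA_real_, length(t)), ch4Cumulative = y,
      incomplete = FALSE)
}

# Brute-force two-segment oracle: exhaustive SSE over every interior knot
# (grid only, no refinement), implemented independently with lm().
oracleTwoSeg <- function(t, y, edgeExclude = 3) {
  cand <- t[(edgeExclude + 1):(length(t) - edgeExclude)]
  sse <- vapply(cand, function(c) {
    sum(resid(lm(y ~ t + pmax(t - c, 0)))^2)
  }, numeric(1))
  list(knot = cand[which(sse <= min(sse) + 1e-12)[1]], sse = min(sse))
}

# A fast-running simulation configuration: two reactors, depletion at day
# 60 with a 120-day horizon (same kinetics as the defaults, compressed
# timeline), noise off unless asked for.
smallSimConfig <- function(reactors = c("R_ctrl", "R_Ni"), horizonDays = 120,
                           depletionDay = 60, noise = FALSE, ...) {
  # the community drift constant scales with the compressed timeline (the
  # depleted phase is ~2.3x shorter than in the full study layout)
  simConfig(reactors = reactors, horizonDays = horizonDays,
            depletionDay = depletionDay,
            pulseDays = numeric(),
            noise = if (noise) list() else list(flowSd = 0, ch4FracSd = 0),
            community = list(driftTau = 500),
            sampleDays = c(20, 40, 55, 70, 85, 100, 110, 118),
            ...)
}

# Three well-separated planar blobs (k-means/CH ground truth k = 3).
makeBlobs <- function(sd = 0.2, n = 20, seed = 5) {
  set.seed(seed)
  rbind(matrix(rnorm(n * 2, 0, sd), ncol = 2),
        matrix(rnorm(n * 2, 6, sd), ncol = 2),
        sweep(matrix(rnorm(n * 2, 0, sd), ncol = 2), 2, c(12, 0), "+"))
}
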