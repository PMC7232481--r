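## Central S4 containers. Vector-slot classes are deliberately lean: each one
## validates the physical invariants of its stream and converts cleanly to a
## data.frame for export.

#' Gas meter / methane sensor time series
#'
#' Fused stream of a volumetric gas meter and an infrared methane sensor:
#' time in minutes since experiment start (strictly increasing), volumetric
#' flow at measurement conditions (mL/min), methane mole fraction in
#' \eqn{[0,1]}, gas temperature (degrees C), pressure (hPa) and a flag marking
#' the stream water-saturated (so that the water vapour partial pressure is
#' subtracted during normalisation to dry normal conditions).
#'
#' @slot time numeric, minutes since start, strictly increasing.
#' @slot flow numeric, mL/min at measurement conditions, non-negative.
#' @slot ch4Fraction numeric in \eqn{[0,1]}.
#' @slot temperature numeric, degrees Celsius, > -273.15.
#' @slot pressure numeric, hPa, positive.
#' @slot waterSaturated logical.
#' @export
setClass("GasTimeSeries",
  representation(
    time = "numeric", flow = "numeric", ch4Fraction = "numeric",
    temperature = "numeric", pressure = "numeric", waterSaturated = "logical"
  )
)

setValidity("GasTimeSeries", function(object) {
  n <- length(object@time)
  msgs <- character()
  lens <- vapply(
    list(object@flow, object@ch4Fraction, object@temperature,
         object@pressure, object@waterSaturated),
    length, integer(1)
  )
  if (any(lens != n)) msgs <- c(msgs, "all slots must have the same length")
  if (n > 1 && any(diff(object@time) <= 0))
    msgs <- c(msgs, "'time' must be strictly increasing")
  if (any(object@flow < 0, na.rm = TRUE)) msgs <- c(msgs, "'flow' must be non-negative")
  if (any(object@ch4Fraction < 0 | object@ch4Fraction > 1, na.rm = TRUE))
    msgs <- c(msgs, "'ch4Fraction' must lie in [0, 1]")
  if (any(object@temperature <= -273.15, na.rm = TRUE))
    msgs <- c(msgs, "'temperature' must exceed absolute zero (-273.15 C)")
  if (any(object@pressure <= 0, na.rm = TRUE)) msgs <- c(msgs, "'pressure' must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a GasTimeSeries
#'
#' Scalar `temperature`, `pressure` and `waterSaturated` are recycled to the
#' length of `time`.
#'
#' @param time minutes since experiment start, strictly increasing.
#' @param flow volumetric flow, mL/min at measurement conditions.
#' @param ch4Fraction methane mole fraction in \eqn{[0,1]}.
#' @param temperature gas temperature, degrees C.
#' @param pressure gas pressure, hPa.
#' @param waterSaturated logical; is the stream water saturated?
#' @return a [GasTimeSeries-class].
#' @examples
#' gts <- gasTimeSeries(0:9, rep(2, 10), rep(0.55, 10))
#' @export
gasTimeSeries <- function(time, flow, ch4Fraction,
                          temperature = 0, pressure = 1013.25,
                          waterSaturated = FALSE) {
  n <- length(time)
  rec <- function(x) if (length(x) == 1L) rep(x, n) else x
  new("GasTimeSeries",
    time = as.numeric(time), flow = as.numeric(rec(flow)),
    ch4Fraction = as.numeric(rec(ch4Fraction)),
    temperature = as.numeric(rec(temperature)),
    pressure = as.numeric(rec(pressure)),
    waterSaturated = as.logical(rec(waterSaturated))
  )
}

#' @describeIn GasTimeSeries-class number of samples
#' @param x a GasTimeSeries
#' @export
setMethod("length", "GasTimeSeries", function(x) length(x@time))

setMethod("show", "GasTimeSeries", function(object) {
  n <- length(object)
  cat("GasTimeSeries with", n, "samples\n")
  if (n) {
    cat(sprintf("  span: %.1f .. %.1f min | flow %.2f .. %.2f mL/min | CH4 %.2f .. %.2f\n",
      min(object@time), max(object@time), min(object@flow), max(object@flow),
      min(object@ch4Fraction), max(object@ch4Fraction)))
  }
})

#' @describeIn GasTimeSeries-class coerce to data.frame
#' @param row.names,optional,... passed on for compatibility; ignored.
#' @export
setMethod("as.data.frame", "GasTimeSeries", function(x, row.names = NULL, optional = FALSE, ...) {
  data.frame(
    time = x@time, flow = x@flow, ch4Fraction = x@ch4Fraction,
    temperature = x@temperature, pressure = x@pressure,
    waterSaturated = x@waterSaturated
  )
})

#' Daily feeding schedule of a CSTBR
#'
#' @slot feedTimes numeric, feeding times in minutes since experiment start
#'   (sorted; typically one per day).
#' @slot reactorVolume numeric, working volume in litres.
#' @slot hrt numeric, hydraulic retention time in days.
#' @slot olr numeric, organic loading rate in gCOD per litre per day.
#' @export
setClass("FeedingSchedule",
  representation(feedTimes = "numeric", reactorVolume = "numeric",
                 hrt = "numeric", olr = "numeric")
)

setValidity("FeedingSchedule", function(object) {
  msgs <- character()
  if (is.unsorted(object@feedTimes, strictly = TRUE))
    msgs <- c(msgs, "'feedTimes' must be strictly increasing")
  if (object@hrt <= 0) msgs <- c(msgs, "'hrt' must be positive")
  if (object@olr <= 0) msgs <- c(msgs, "'olr' must be positive")
  if (object@reactorVolume <= 0) msgs <- c(msgs, "'reactorVolume' must be positive")
  if (length(msgs)) msgs else TRUE
})

#' Construct a FeedingSchedule
#'
#' @param feedTimes feeding times, minutes since experiment start.
#' @param reactorVolume working volume, litres.
#' @param hrt hydraulic retention time, days.
#' @param olr organic loading rate, gCOD L^-1 d^-1.
#' @return a [FeedingSchedule-class].
#' @examples
#' sched <- feedingSchedule(seq(0, 9 * 1440, by = 1440))
#' feedCod(sched)  # gCOD per litre of feed = OLR x HRT
#' @export
feedingSchedule <- function(feedTimes, reactorVolume = 4, hrt = 30, olr = 1.7) {
  new("FeedingSchedule", feedTimes = as.numeric(feedTimes),
      reactorVolume = reactorVolume, hrt = hrt, olr = olr)
}

#' Feed COD concentration implied by a schedule
#'
#' The chemically defined feed concentration in gCOD per litre equals
#' OLR x HRT exactly (a reactor fed V/HRT litres per day at OLR gCOD/L/d).
#'
#' @param schedule a [FeedingSchedule-class].
#' @return gCOD per litre of feed.
#' @export
feedCod <- function(schedule) schedule@olr * schedule@hrt

setMethod("show", "FeedingSchedule", function(object) {
  cat(sprintf("FeedingSchedule: %d feeds | V = %g L | HRT = %g d | OLR = %g gCOD/L/d | feed COD = %g g/L\n",
    length(object@feedTimes), object@reactorVolume, object@hrt, object@olr,
    feedCod(object)))
})

#' One feeding cycle of normalised methane production
#'
#' @slot cycleDay integer day index of the feeding event.
#' @slot tRel numeric, minutes after feeding in \eqn{[0, 1440]}.
#' @slot ch4Rate numeric, mL CH4/min at dry normal conditions.
#' @slot ch4Cumulative numeric, mL CH4 integrated from feeding (trapezoid).
#' @slot incomplete logical flag; TRUE when the cycle contains a sampling gap
#'   longer than 30 min (such cycles are excluded from breakpoint trending).
#' @export
setClass("DailyCycle",
  representation(cycleDay = "integer", tRel = "numeric", ch4Rate = "numeric",
                 ch4Cumulative = "numeric", incomplete = "logical")
)

setValidity("DailyCycle", function(object) {
  msgs <- character()
  if (length(object@tRel) != length(object@ch4Rate) ||
      length(object@tRel) != length(object@ch4Cumulative))
    msgs <- c(msgs, "tRel, ch4Rate and ch4Cumulative must have equal length")
  if (any(object@tRel < 0 | object@tRel > 1440))
    msgs <- c(msgs, "'tRel' must lie within [0, 1440] minutes")
  if (any(diff(object@ch4Cumulative) < -1e-8))
    msgs <- c(msgs, "'ch4Cumulative' must be non-decreasing")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "DailyCycle", function(object) {
  cat(sprintf("DailyCycle day %d: %d samples, %.0f mL CH4 over %.0f min%s\n",
    object@cycleDay, length(object@tRel),
    if (length(object@ch4Cumulative)) max(object@ch4Cumulative) else 0,
    if (length(object@tRel)) max(object@tRel) else 0,
    if (object@incomplete) " [incomplete]" else ""))
})

#' Two-segment breakpoint fit of one feeding cycle
#'
#' A continuous two-piece linear model of cumulative methane versus time
#' after feeding. The knot is the transition of methane production from its
#' active to its residual level.
#'
#' @slot cycleDay integer.
#' @slot knot numeric, minutes after feeding.
#' @slot slopeActive numeric, mL/min before the knot.
#' @slot slopeResidual numeric, mL/min after the knot.
#' @slot intercept numeric, mL at t = 0.
#' @slot sse numeric, residual sum of squares (mL^2).
#' @slot censored logical; knot pinned at the window edge.
#' @slot degenerate logical; no two-segment structure (improvement over a
#'   single line below 1 percent).
#' @export
setClass("BreakpointFit",
  representation(cycleDay = "integer", knot = "numeric", slopeActive = "numeric",
                 slopeResidual = "numeric", intercept = "numeric", sse = "numeric",
                 censored = "logical", degenerate = "logical")
)

setValidity("BreakpointFit", function(object) {
  msgs <- character()
  if (object@sse < 0) msgs <- c(msgs, "'sse' must be non-negative")
  if (!object@censored && !object@degenerate &&
      (object@knot <= 0 || object@knot > 1440))
    msgs <- c(msgs, "'knot' must lie in (0, 1440] unless censored")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn BreakpointFit-class knot accessor
#' @param object a BreakpointFit
#' @export
setMethod("knot", "BreakpointFit", function(object) object@knot)

setMethod("show", "BreakpointFit", function(object) {
  cat(sprintf("BreakpointFit day %d: knot = %.1f min, slopes %.3f -> %.3f mL/min, SSE = %.3g%s%s\n",
    object@cycleDay, object@knot, object@slopeActive, object@slopeResidual,
    object@sse, if (object@censored) " [censored]" else "",
    if (object@degenerate) " [degenerate]" else ""))
})

#' Day-by-day drift of the breakpoint statistic
#'
#' @slot entries data.frame with columns `day`, `knot` (minutes; censored
#'   entries recorded at 1440), `censored`, `driftSlope` (least-squares slope
#'   of knot versus day over the trailing window, min/day).
#' @slot window numeric, trailing window in days used for `driftSlope`.
#' @slot alarmDay numeric day on which the alarm criterion first held, or
#'   `NA` when it never did.
#' @export
setClass("BreakpointTrend",
  representation(entries = "data.frame", window = "numeric", alarmDay = "numeric")
)

setValidity("BreakpointTrend", function(object) {
  msgs <- character()
  need <- c("day", "knot", "censored", "driftSlope")
  if (!all(need %in% names(object@entries)))
    msgs <- c(msgs, paste("'entries' must have columns", paste(need, collapse = ", ")))
  else if (is.unsorted(object@entries$day, strictly = TRUE))
    msgs <- c(msgs, "'entries$day' must be strictly increasing")
  if (!is.na(object@alarmDay) && nrow(object@entries) &&
      !(object@alarmDay %in% object@entries$day))
    msgs <- c(msgs, "'alarmDay' must be one of the entry days")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn BreakpointTrend-class alarm day accessor
#' @param object a BreakpointTrend
#' @export
setMethod("alarmDay", "BreakpointTrend", function(object) object@alarmDay)

setMethod("show", "BreakpointTrend", function(object) {
  cat(sprintf("BreakpointTrend: %d days", nrow(object@entries)))
  if (nrow(object@entries))
    cat(sprintf(" (%d .. %d), knots %.0f .. %.0f min",
      min(object@entries$day), max(object@entries$day),
      min(object@entries$knot), max(object@entries$knot)))
  if (!is.na(object@alarmDay)) cat(sprintf(" | ALARM on day %d", as.integer(object@alarmDay)))
  cat("\n")
})

#' Trace-element dosing history of one reactor
#'
#' Piecewise-constant feed concentration (steps) plus instantaneous pulse
#' additions, together with the hydraulic retention time that sets the
#' washout time constant.
#'
#' @slot element character, one of Co, Ni, Se, W.
#' @slot events data.frame with columns `time` (days, sorted), `kind`
#'   ("step" or "pulse") and `value` (nM feed concentration for steps, nM
#'   instantaneous reactor increment for pulses).
#' @slot hrt numeric, days.
#' @slot initialConc numeric, reactor concentration at time 0 (nM).
#' @slot initialFeed numeric, feed concentration before the first step (nM);
#'   defaults to `initialConc` (steady state).
#' @export
setClass("TEDosingHistory",
  representation(element = "character", events = "data.frame", hrt = "numeric",
                 initialConc = "numeric", initialFeed = "numeric")
)

setValidity("TEDosingHistory", function(object) {
  msgs <- character()
  if (!object@element %in% c("Co", "Ni", "Se", "W"))
    msgs <- c(msgs, "'element' must be one of Co, Ni, Se, W")
  ev <- object@events
  if (nrow(ev)) {
    if (!all(c("time", "kind", "value") %in% names(ev)))
      msgs <- c(msgs, "'events' needs columns time, kind, value")
    else {
      if (is.unsorted(ev$time)) msgs <- c(msgs, "'events$time' must be sorted")
      if (!all(ev$kind %in% c("step", "pulse")))
        msgs <- c(msgs, "'events$kind' must be 'step' or 'pulse'")
      if (any(ev$value < 0)) msgs <- c(msgs, "'events$value' must be non-negative")
    }
  }
  if (object@hrt <= 0) msgs <- c(msgs, "'hrt' must be positive")
  if (object@initialConc < 0) msgs <- c(msgs, "'initialConc' must be non-negative")
  if (length(msgs)) msgs else TRUE
})

#' Construct a TEDosingHistory
#'
#' @param element "Co", "Ni", "Se" or "W".
#' @param initialConc reactor concentration at day 0, nM.
#' @param events data.frame(time, kind, value); see
#'   [TEDosingHistory-class].
#' @param hrt hydraulic retention time, days.
#' @param initialFeed feed concentration before the first step event (nM);
#'   defaults to `initialConc`, i.e. the reactor starts at steady state.
#' @return a [TEDosingHistory-class].
#' @examples
#' ni <- teDosingHistory("Ni", 0.13,
#'   events = data.frame(time = 206, kind = "step", value = 0))
#' concentrationAt(ni, c(229, 257))
#' @export
teDosingHistory <- function(element, initialConc, events = NULL, hrt = 30,
                            initialFeed = initialConc) {
  if (is.null(events))
    events <- data.frame(time = numeric(), kind = character(), value = numeric())
  new("TEDosingHistory", element = element, events = events, hrt = hrt,
      initialConc = initialConc, initialFeed = initialFeed)
}

setMethod("show", "TEDosingHistory", function(object) {
  cat(sprintf("TEDosingHistory [%s]: C0 = %g nM, feed0 = %g nM, HRT = %g d, %d event(s)\n",
    object@element, object@initialConc, object@initialFeed, object@hrt,
    nrow(object@events)))
})

#' Trace-element concentration series
#'
#' @slot element character.
#' @slot series data.frame with columns `day` and `nM`.
#' @export
setClass("TEConcentrationSeries",
  representation(element = "character", series = "data.frame")
)

setValidity("TEConcentrationSeries", function(object) {
  msgs <- character()
  if (!all(c("day", "nM") %in% names(object@series)))
    msgs <- c(msgs, "'series' needs columns day, nM")
  else if (any(object@series$nM < -1e-12))
    msgs <- c(msgs, "concentrations must be non-negative")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "TEConcentrationSeries", function(object) {
  s <- object@series
  cat(sprintf("TEConcentrationSeries [%s]: %d points, day %g .. %g, %0.3g .. %0.3g nM\n",
    object@element, nrow(s), min(s$day), max(s$day), min(s$nM), max(s$nM)))
})

#' @describeIn TEConcentrationSeries-class coerce to data.frame
#' @param x a TEConcentrationSeries
#' @param row.names,optional,... ignored.
#' @export
setMethod("as.data.frame", "TEConcentrationSeries",
  function(x, row.names = NULL, optional = FALSE, ...) x@series)

#' Substrate-component trace-element contribution table
#'
#' Rows are substrate components, columns the elements Co, Ni, Se, W;
#' entries are ng per litre of substrate.
#'
#' @slot contributions numeric matrix, components x elements, ng/L.
#' @export
setClass("SubstrateTable", representation(contributions = "matrix"))

setValidity("SubstrateTable", function(object) {
  msgs <- character()
  m <- object@contributions
  if (!is.numeric(m)) msgs <- c(msgs, "'contributions' must be numeric")
  else {
    if (any(m < 0)) msgs <- c(msgs, "contributions must be non-negative")
    if (is.null(colnames(m)) || !all(colnames(m) %in% c("Co", "Ni", "Se", "W")))
      msgs <- c(msgs, "columns must be named from Co, Ni, Se, W")
  }
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "SubstrateTable", function(object) {
  cat("SubstrateTable (ng per L of substrate)\n")
  print(object@contributions)
})

#' ASV count table with taxonomy and sample metadata
#'
#' Thin wrapper around [SummarizedExperiment::SummarizedExperiment] with one
#' `counts` assay (taxa as rows, samples as columns), taxonomy ranks in
#' `rowData` and per-sample `reactor` and `day` in `colData`.
#'
#' @export
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
setClass("ASVExperiment", contains = "SummarizedExperiment")

setValidity("ASVExperiment", function(object) {
  msgs <- character()
  if (!"counts" %in% SummarizedExperiment::assayNames(object))
    return("must carry a 'counts' assay")
  m <- SummarizedExperiment::assay(object, "counts")
  if (any(m < 0)) msgs <- c(msgs, "counts must be non-negative")
  if (any(abs(m - round(m)) > 1e-8)) msgs <- c(msgs, "counts must be integers")
  if (anyDuplicated(colnames(m))) msgs <- c(msgs, "duplicate sample ids")
  if (ncol(SummarizedExperiment::rowData(object)) > 7)
    msgs <- c(msgs, "taxonomy may have at most 7 ranks")
  if (length(msgs)) msgs else TRUE
})

#' Construct an ASVExperiment
#'
#' @param counts matrix of non-negative integer counts. Orientation is
#'   detected from `metadata`: rows whose names match `metadata` sample ids
#'   are treated as samples and the matrix is transposed to taxa x samples.
#' @param taxonomy data.frame of rank columns (up to domain..genus/species,
#'   max 7) with one row per taxon, or a character vector of
#'   semicolon-delimited rank strings.
#' @param metadata data.frame with one row per sample; must contain columns
#'   `reactor` and `day`. Row names (or a `sample` column) give sample ids.
#' @return an [ASVExperiment-class].
#' @export
asvExperiment <- function(counts, taxonomy = NULL, metadata = NULL) {
  counts <- as.matrix(counts)
  if (is.null(metadata)) {
    metadata <- data.frame(reactor = rep(NA_character_, ncol(counts)),
                           day = rep(NA_real_, ncol(counts)))
    rownames(metadata) <- colnames(counts)
  }
  if (!is.null(metadata$sample)) rownames(metadata) <- metadata$sample
  ids <- rownames(metadata)
  if (!is.null(rownames(counts)) && !is.null(ids) &&
      all(ids %in% rownames(counts)) && !all(ids %in% colnames(counts))) {
    counts <- t(counts)  # was samples x taxa
  }
  if (is.null(colnames(counts))) colnames(counts) <- ids
  counts <- counts[, ids, drop = FALSE]
  if (is.character(taxonomy)) taxonomy <- splitTaxonomy(taxonomy)
  if (is.null(taxonomy))
    taxonomy <- data.frame(row.names = rownames(counts))
  storage.mode(counts) <- "integer"
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts),
    rowData = S4Vectors::DataFrame(taxonomy),
    colData = S4Vectors::DataFrame(metadata)
  )
  new("ASVExperiment", se)
}

#' Split semicolon-delimited taxonomy strings into rank columns
#'
#' @param x character vector like
#'   `"Bacteria;Firmicutes;Clostridia;...;Lachnospiraceae NK3A20"`.
#' @param ranks rank names to assign, outermost first.
#' @return data.frame with one column per rank.
#' @export
splitTaxonomy <- function(x, ranks = c("domain", "phylum", "class", "order",
                                       "family", "genus", "species")) {
  parts <- strsplit(x, ";", fixed = TRUE)
  depth <- min(max(lengths(parts)), length(ranks))
  out <- lapply(seq_len(depth), function(i)
    vapply(parts, function(p) if (length(p) >= i) trimws(p[[i]]) else NA_character_,
           character(1)))
  names(out) <- ranks[seq_len(depth)]
  as.data.frame(out, stringsAsFactors = FALSE)
}

#' NMDS ordination result
#'
#' @slot coordinates numeric matrix, samples x dims, centred.
#' @slot stress numeric, Kruskal stress-1 (fraction in \eqn{[0,1]}).
#' @slot converged logical.
#' @slot seed integer seed used for the restarts.
#' @export
setClass("OrdinationResult",
  representation(coordinates = "matrix", stress = "numeric",
                 converged = "logical", seed = "integer")
)

setValidity("OrdinationResult", function(object) {
  if (object@stress < 0) "stress must be non-negative" else TRUE
})

setMethod("show", "OrdinationResult", function(object) {
  cat(sprintf("OrdinationResult: %d samples in %d dims, stress = %.4g%s\n",
    nrow(object@coordinates), ncol(object@coordinates), object@stress,
    if (object@converged) "" else " [not converged]"))
})

#' K-means clustering result with model-order selection
#'
#' @slot k integer, chosen number of clusters.
#' @slot labels integer vector of cluster labels in 1..k.
#' @slot chIndex named numeric, Calinski-Harabasz statistic per candidate k.
#' @slot chosenKRule character, how k was chosen.
#' @slot weakStructure logical; TRUE when the CH curve shows no pronounced
#'   optimum (k is then reported as 2 for inspection only).
#' @slot dendrogram the Bray-Curtis hierarchical clustering emitted as a side
#'   artifact (an `hclust` object), or NULL.
#' @export
setClass("ClusterResult",
  representation(k = "integer", labels = "integer", chIndex = "numeric",
                 chosenKRule = "character", weakStructure = "logical",
                 dendrogram = "ANY")
)

setValidity("ClusterResult", function(object) {
  msgs <- character()
  if (object@k < 2) msgs <- c(msgs, "'k' must be at least 2")
  if (length(object@labels) &&
      (min(object@labels) < 1 || max(object@labels) > object@k))
    msgs <- c(msgs, "labels must lie in 1..k")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "ClusterResult", function(object) {
  cat(sprintf("ClusterResult: k = %d (%s)%s | CH: %s\n",
    object@k, object@chosenKRule,
    if (object@weakStructure) " [weak structure]" else "",
    paste(sprintf("k%s=%.1f", names(object@chIndex), object@chIndex), collapse = " ")))
})

#' Indicator value (IndVal) analysis result
#'
#' Dufrene-Legendre indicator values per genus and cluster: specificity A,
#' fidelity B, indval = 100 A B, and a one-sided permutation p-value for each
#' genus' best cluster.
#'
#' @slot table data.frame with columns `taxon`, `cluster`, `A`, `B`, `indval`.
#' @slot pValues data.frame with columns `taxon`, `cluster` (argmax),
#'   `indval` (observed max), `p`.
#' @slot nPerm integer.
#' @slot seed integer.
#' @export
setClass("IndValResult",
  representation(table = "data.frame", pValues = "data.frame",
                 nPerm = "integer", seed = "integer")
)

setMethod("show", "IndValResult", function(object) {
  sig <- sum(object@pValues$p <= 0.05)
  cat(sprintf("IndValResult: %d taxa x %d clusters, %d permutations; %d taxa with p <= 0.05\n",
    length(unique(object@table$taxon)), length(unique(object@table$cluster)),
    object@nPerm, sig))
})

#' Synthetic digester simulation bundle
#'
#' Coherent synthetic outputs of one seeded simulation: minute-resolution gas
#' streams at meter conditions, weekly VFA profiles, trace-element
#' concentration series, a daily pH proxy, drifting ASV tables, the COD
#' ledger of the noise-free core, and the logged ground-truth events.
#'
#' @slot gas named list of [GasTimeSeries-class], one per reactor.
#' @slot vfa data.frame: reactor, day, acid, mM (weekly pre-feed samples).
#' @slot te named list (per reactor) of lists of
#'   [TEConcentrationSeries-class] per element.
#' @slot ph data.frame: reactor, day, ph.
#' @slot asv an [ASVExperiment-class] of bacterial communities.
#' @slot asvArchaea an [ASVExperiment-class] of archaeal communities.
#' @slot events data.frame: reactor, event, day (ground truth logged by the
#'   noise-free core: residual-transition drift, propionate/acetate/butyrate
#'   onsets, failure).
#' @slot ledger data.frame: daily COD balance per reactor.
#' @slot transitions data.frame: reactor, day, minute of the true transition
#'   to residual methane production (the simulator's built-in breakpoint).
#' @slot config the [SimConfig-class] used.
#' @slot seed integer.
#' @export
setClass("SimBundle",
  representation(gas = "list", vfa = "data.frame", te = "list",
                 ph = "data.frame", asv = "ANY", asvArchaea = "ANY",
                 events = "data.frame", ledger = "data.frame",
                 transitions = "data.frame", config = "ANY", seed = "integer")
)

#' @describeIn SimBundle-class logged events accessor
#' @param object a SimBundle
#' @export
setMethod("simEvents", "SimBundle", function(object) object@events)

setMethod("show", "SimBundle", function(object) {
  cat(sprintf("SimBundle (seed %d): %d reactor(s): %s\n", object@seed,
    length(object@gas), paste(names(object@gas), collapse = ", ")))
  if (nrow(object@events)) {
    cat("  events:\n")
    ev <- object@events
    for (r in unique(ev$reactor))
      cat(sprintf("    %s: %s\n", r,
        paste(sprintf("%s=%g", ev$event[ev$reactor == r], ev$day[ev$reactor == r]),
              collapse = ", ")))
  }
})

#' Pipeline run report
#'
#' @slot sections named list of per-stage summaries.
#' @slot provenance list: seed, package version, echoed configuration.
#' @export
setClass("RunReport", representation(sections = "list", provenance = "list"))

setMethod("show", "RunReport", function(object) {
  cat("RunReport with sections:", paste(names(object@sections), collapse = ", "), "\n")
  cat("  seed:", object@provenance$seed, "| cstbr", as.character(object@provenance$version), "\n")
})
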