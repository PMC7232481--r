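#' @import methods
NULL

#' Fit a continuous two-segment line to a feeding cycle
#'
#' @param cycle a [DailyCycle-class] (or an object coercible to one).
#' @param ... passed to methods.
#' @return a [BreakpointFit-class].
#' @export
setGeneric("fitTwoSegment", function(cycle, ...) standardGeneric("fitTwoSegment"))

#' Reactor concentration of a dosed trace element at given times
#'
#' @param history a [TEDosingHistory-class].
#' @param t time(s) in days since experiment start.
#' @param ... passed to methods.
#' @return numeric vector of concentrations (nM).
#' @export
setGeneric("concentrationAt", function(history, t, ...) standardGeneric("concentrationAt"))

#' Knot (breakpoint) accessor
#' @param object an object with a breakpoint.
#' @return numeric, minutes after feeding.
#' @export
setGeneric("knot", function(object) standardGeneric("knot"))

#' Alarm day accessor
#' @param object an object carrying an alarm state.
#' @return integer day or `NA` when no alarm was raised.
#' @export
setGeneric("alarmDay", function(object) standardGeneric("alarmDay"))

#' Ground-truth and logged events of a simulation
#' @param object a [SimBundle-class].
#' @return a data.frame of events per reactor.
#' @export
setGeneric("simEvents", function(object) standardGeneric("simEvents"))
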