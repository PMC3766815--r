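#' Accessor generics for circafly containers
#'
#' Small accessor layer over the S4 slots so user code never touches slots
#' directly: \code{flyId} and \code{binMinutes} for activity series,
#' \code{activityCounts} / \code{flaggedBins} for the count grid,
#' \code{schedule} for the attached light schedule, \code{exprFloor} for the
#' expression floor of a study.
#'
#' @param x a circafly object
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("flyId", function(x) standardGeneric("flyId"))
#' @rdname accessors
#' @export
setGeneric("binMinutes", function(x) standardGeneric("binMinutes"))
#' @rdname accessors
#' @export
setGeneric("activityCounts", function(x) standardGeneric("activityCounts"))
#' @rdname accessors
#' @export
setGeneric("flaggedBins", function(x) standardGeneric("flaggedBins"))
#' @rdname accessors
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))
#' @rdname accessors
#' @export
setGeneric("exprFloor", function(x) standardGeneric("exprFloor"))

#' @rdname accessors
setMethod("flyId", "ActivitySeries", function(x) x@flyId)
#' @rdname accessors
setMethod("flyId", "LuciferaseTrace", function(x) x@flyId)
#' @rdname accessors
setMethod("binMinutes", "ActivitySeries", function(x) x@binMin)
#' @rdname accessors
setMethod("activityCounts", "ActivitySeries", function(x) x@counts)
#' @rdname accessors
setMethod("flaggedBins", "ActivitySeries", function(x) x@flagged)
#' @rdname accessors
setMethod("schedule", "ActivitySeries", function(x) x@schedule)
#' @rdname accessors
setMethod("exprFloor", "ExpressionStudy", function(x) x@floor)

#' Duration of a light schedule in minutes
#' @param x a \code{LightSchedule}
#' @return total duration (LD + DD days) in minutes
#' @export
scheduleDurationMin <- function(x) {
  (x@nDaysLD + x@nDaysDD) * 1440
}

#' Per-bin lights-on mask for a schedule
#'
#' TRUE for bins whose start falls during lights-on of an LD day; all DD-day
#' bins are FALSE.  Bin starts are at ZT0 of day 1 and advance by
#' \code{binMin} minutes.
#'
#' @param x a \code{LightSchedule}
#' @param binMin minutes per bin
#' @return logical vector, one element per bin of the schedule
#' @export
lightsOnMask <- function(x, binMin) {
  nBins <- scheduleDurationMin(x) / binMin
  if (nBins != round(nBins))
    stop("schedule duration is not a whole number of ", binMin, "-min bins")
  startMin <- (seq_len(nBins) - 1L) * binMin
  day <- startMin %/% 1440
  zt <- (startMin %% 1440) / 60
  day < x@nDaysLD & zt < x@photoperiodH
}

#' Light-transition events of a schedule
#'
#' Lights-on and lights-off event times for every LD day, in minutes from
#' the start of the recording (ZT0 of day 1).  The first lights-on event sits
#' at minute 0 and is reported but usually unusable for pre/post scoring
#' because it lacks a pre-event window.
#'
#' @param x a \code{LightSchedule}
#' @return data.frame with columns \code{kind} ("lights_on"/"lights_off") and
#'   \code{timeMin}
#' @export
lightTransitions <- function(x) {
  if (x@nDaysLD < 1L)
    return(data.frame(kind = character(0), timeMin = numeric(0)))
  days <- seq_len(x@nDaysLD) - 1L
  out <- data.frame(
    kind = rep(c("lights_on", "lights_off"), each = length(days)),
    timeMin = c(days * 1440, days * 1440 + x@photoperiodH * 60))
  out[order(out$timeMin), , drop = FALSE]
}

setMethod("show", "LightSchedule", function(object) {
  cat(sprintf(
    "LightSchedule: %d LD day(s) (%g h photoperiod, lights-on %02.0f:%02.0f) + %d DD day(s)\n",
    object@nDaysLD, object@photoperiodH,
    floor(object@lightsOnClock),
    (object@lightsOnClock %% 1) * 60, object@nDaysDD))
})

setMethod("show", "ActivitySeries", function(object) {
  cat(sprintf("ActivitySeries '%s': %d bins of %d min (total %d counts",
              object@flyId, length(object@counts), object@binMin,
              sum(object@counts)))
  nf <- sum(object@flagged)
  if (nf) cat(sprintf(", %d flagged bins", nf))
  cat(")\n")
  if (!is.null(object@schedule)) show(object@schedule)
})

setMethod("show", "LuciferaseTrace", function(object) {
  cat(sprintf("LuciferaseTrace '%s': %d reads over %.1f h, %s%s%s\n",
              object@flyId, length(object@values),
              diff(range(object@timesH)),
              if (object@alive) "alive" else "dead",
              if (length(object@detrended)) ", detrended" else "",
              if (length(object@fit)) ", cosinor-fitted" else ""))
})

setMethod("show", "SurvivalCohort", function(object) {
  cat(sprintf("SurvivalCohort '%s': %d vial(s) x %d flies, horizon %d d\n",
              object@genotype, ncol(object@vials), object@n0,
              object@horizonD))
})

setMethod("show", "ExpressionStudy", function(object) {
  cat(sprintf("ExpressionStudy: %d genes x %d samples (log2 floor %.1f)\n",
              nrow(object), ncol(object), object@floor))
  cd <- SummarizedExperiment::colData(object)
  cat("  design: ")
  print(table(genotype = cd$genotype, timepoint = cd$timepoint))
})
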