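# Acute light-transition responses and day/night activity partitioning.
# Scoring uses 1-min bins: total beam breaks in the 10 min before vs the 10
# min after each lights-on / lights-off event; a fly responds to an event
# when the differential (post - pre) strictly exceeds 2 counts.  Bins are
# half-open, so the bin starting at the event belongs to the post window.

#' Score one light-transition event for one fly
#'
#' @param series an \code{ActivitySeries} at 1-min bins
#' @param eventMin event time in minutes from the series start (must fall on
#'   a bin edge)
#' @param eventKind "lights_on" or "lights_off"
#' @param windowMin half-window length in minutes (default 10)
#' @param responderThreshold counts the differential must strictly exceed
#'   (default 2)
#' @return one-row data.frame: flyId, eventKind, eventMin, preCounts,
#'   postCounts, differential, responder, valid, reason
#' @export
scoreTransition <- function(series, eventMin, eventKind,
                            windowMin = 10, responderThreshold = 2) {
  if (series@binMin != 1L)
    stop("transition scoring needs 1-min bins; record at 1-min resolution ",
         "or do not re-bin (got ", series@binMin, "-min bins)")
  if (eventMin %% 1 != 0)
    stop("event at minute ", eventMin, " does not fall on a bin edge")
  eventKind <- match.arg(eventKind, c("lights_on", "lights_off"))
  n <- length(series@counts)
  invalid <- function(reason) {
    data.frame(flyId = series@flyId, eventKind = eventKind,
               eventMin = eventMin, preCounts = NA_integer_,
               postCounts = NA_integer_, differential = NA_integer_,
               responder = NA, valid = FALSE, reason = reason,
               stringsAsFactors = FALSE)
  }
  preIdx <- (eventMin - windowMin + 1):eventMin        # bins [e-10, e)
  postIdx <- (eventMin + 1):(eventMin + windowMin)     # bins [e, e+10)
  if (preIdx[1] < 1 || postIdx[windowMin] > n)
    return(invalid("window truncated by recording edge"))
  if (any(series@flagged[c(preIdx, postIdx)]))
    return(invalid("flagged bins inside scoring window"))
  pre <- sum(series@counts[preIdx])
  post <- sum(series@counts[postIdx])
  d <- post - pre
  data.frame(flyId = series@flyId, eventKind = eventKind,
             eventMin = eventMin, preCounts = pre, postCounts = post,
             differential = d, responder = d > responderThreshold,
             valid = TRUE, reason = "", stringsAsFactors = FALSE)
}

#' Score every schedule transition for a cohort
#'
#' Runs \code{\link{scoreTransition}} for each lights-on and lights-off
#' event of each fly's attached schedule.  Events whose windows are
#' truncated (e.g. the lights-on at recording start) are kept with
#' \code{valid = FALSE} and a reason.
#'
#' @param seriesList list of 1-min \code{ActivitySeries} with schedules
#' @inheritParams scoreTransition
#' @return data.frame of per-fly, per-event scores
#' @export
scoreAllTransitions <- function(seriesList, windowMin = 10,
                                responderThreshold = 2) {
  do.call(rbind, lapply(seriesList, function(s) {
    sch <- s@schedule
    if (is.null(sch)) stop("series '", s@flyId, "' has no schedule")
    tr <- lightTransitions(sch)
    do.call(rbind, lapply(seq_len(nrow(tr)), function(i) {
      scoreTransition(s, tr$timeMin[i], tr$kind[i], windowMin = windowMin,
                      responderThreshold = responderThreshold)
    }))
  }))
}

#' Cohort summary of transition responses
#'
#' Restricts to events within the last \code{lastNDays} days of the
#' recording window covered by the scores, then aggregates per fly and
#' event kind: a fly counts as a responder for a kind when it responds on a
#' strict majority of its valid events of that kind, and its amplitude is
#' the mean differential over those events.  Group outputs are the
#' responder fraction with a binomial (Wald) CI and the mean amplitude with
#' SEM.
#'
#' @param scores data.frame from \code{\link{scoreAllTransitions}}
#' @param lastNDays number of trailing days of events to use (default 4)
#' @return data.frame, one row per event kind: nFlies, nResponders,
#'   responderFraction, fracLo, fracHi, meanAmplitude, amplitudeSem
#' @export
summarizeTransitions <- function(scores, lastNDays = 4) {
  lastMin <- max(scores$eventMin)
  cut <- (lastMin %/% 1440 - lastNDays + 1) * 1440
  w <- scores[scores$eventMin >= cut & scores$valid, , drop = FALSE]
  if (!nrow(w)) stop("no valid events in the last ", lastNDays, " days")
  out <- lapply(split(w, w$eventKind), function(d) {
    perFly <- lapply(split(d, d$flyId), function(f) {
      data.frame(responder = mean(f$responder) > 0.5,
                 amplitude = mean(f$differential))
    })
    perFly <- do.call(rbind, perFly)
    n <- nrow(perFly)
    p <- mean(perFly$responder)
    se <- sqrt(p * (1 - p) / n)
    data.frame(eventKind = d$eventKind[1], nFlies = n,
               nResponders = sum(perFly$responder),
               responderFraction = p,
               fracLo = max(0, p - 1.96 * se),
               fracHi = min(1, p + 1.96 * se),
               meanAmplitude = mean(perFly$amplitude),
               amplitudeSem = sd(perFly$amplitude) / sqrt(n))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Day/night activity partition of one fly
#'
#' Totals beam breaks over lights-on vs lights-off bins of complete LD days
#' and forms the day/night ratio.  When the night total is zero the ratio is
#' flagged undefined rather than reported as infinity.
#'
#' @param series an \code{ActivitySeries}
#' @param schedule optional schedule (defaults to the attached one)
#' @return one-row data.frame: flyId, dayTotal, nightTotal, overallTotal,
#'   ratio, ratioDefined
#' @export
dayNightRatio <- function(series, schedule = NULL) {
  if (is.null(schedule)) schedule <- series@schedule
  if (is.null(schedule)) stop("no light schedule available")
  if (schedule@nDaysLD < 1L)
    stop("no complete LD day in the schedule")
  binMin <- series@binMin
  ldBins <- schedule@nDaysLD * 1440 %/% binMin
  if (length(series@counts) < ldBins)
    stop("series does not cover the LD block")
  onMask <- lightsOnMask(schedule, binMin)[seq_len(ldBins)]
  counts <- series@counts[seq_len(ldBins)]
  dayTotal <- sum(counts[onMask])
  nightTotal <- sum(counts[!onMask])
  data.frame(flyId = series@flyId, dayTotal = dayTotal,
             nightTotal = nightTotal, overallTotal = dayTotal + nightTotal,
             ratio = if (nightTotal > 0) dayTotal / nightTotal else
               NA_real_,
             ratioDefined = nightTotal > 0, stringsAsFactors = FALSE)
}
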