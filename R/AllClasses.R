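#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#' @importFrom S4Vectors DataFrame
#' @importFrom stats acf aggregate approx coef complete.cases cor lm median
#'   p.adjust pf pnorm quantile rbinom rnorm rpois runif rweibull sd var
#' @importFrom utils read.delim write.csv write.table head tail
NULL

setClassUnion("POSIXctOrNULL", c("POSIXct", "NULL"))

#' Light schedule for an activity or reporter experiment
#'
#' Describes a standard entrainment protocol: \code{nDaysLD} days of
#' light:dark cycling (lights on for \code{photoperiodH} hours starting at
#' clock time \code{lightsOnClock}), followed contiguously by \code{nDaysDD}
#' days of constant darkness.  Zeitgeber time is defined with ZT0 = lights-on.
#'
#' @slot lightsOnClock clock time of lights-on, hours in [0, 24)
#' @slot photoperiodH hours of light per LD day, in (0, 24)
#' @slot nDaysLD,nDaysDD integer day counts; DD days follow LD days
#' @export
setClass("LightSchedule",
  representation(
    lightsOnClock = "numeric",
    photoperiodH  = "numeric",
    nDaysLD       = "integer",
    nDaysDD       = "integer"
  )
)

setValidity("LightSchedule", function(object) {
  msg <- character()
  if (length(object@photoperiodH) != 1 || !is.finite(object@photoperiodH) ||
      object@photoperiodH <= 0 || object@photoperiodH >= 24)
    msg <- c(msg, "photoperiodH must be a single value in (0, 24)")
  if (length(object@lightsOnClock) != 1 || !is.finite(object@lightsOnClock) ||
      object@lightsOnClock < 0 || object@lightsOnClock >= 24)
    msg <- c(msg, "lightsOnClock must be a single value in [0, 24)")
  if (object@nDaysLD < 0L || object@nDaysDD < 0L)
    msg <- c(msg, "day counts must be non-negative")
  if (object@nDaysLD + object@nDaysDD < 1L)
    msg <- c(msg, "schedule must span at least one day")
  if (length(msg)) msg else TRUE
})

#' @param lightsOnClock clock time of lights-on in hours (default 8)
#' @param photoperiodH light hours per LD day (default 12)
#' @param nDaysLD,nDaysDD number of light:dark and constant-darkness days
#' @return a \code{LightSchedule}
#' @rdname LightSchedule-class
#' @examples
#' lightSchedule(nDaysLD = 3, nDaysDD = 7)
#' @export
lightSchedule <- function(nDaysLD, nDaysDD, photoperiodH = 12,
                          lightsOnClock = 8) {
  new("LightSchedule",
      lightsOnClock = as.numeric(lightsOnClock),
      photoperiodH  = as.numeric(photoperiodH),
      nDaysLD       = as.integer(nDaysLD),
      nDaysDD       = as.integer(nDaysDD))
}

setClassUnion("LightScheduleOrNULL", c("LightSchedule", "NULL"))

#' Single-fly beam-break activity series
#'
#' One fly's beam-break counts on a uniform time grid of \code{binMin}-minute
#' bins, aligned to a \code{\linkS4class{LightSchedule}} so that the first bin
#' starts at ZT0 (lights-on) of the first scheduled day.  Bins are half-open
#' \code{[start, start + binMin)}.  \code{flagged} marks bins read from
#' monitor rows with a non-OK status; such bins are retained here and handled
#' (imputed or excluded) by downstream analyses, never silently dropped.
#'
#' @slot flyId character identifier
#' @slot t0 absolute start time of the first bin (or NULL if unknown)
#' @slot binMin minutes per bin (1 or 5 in the supported protocols)
#' @slot counts non-negative integer beam-break counts, one per bin
#' @slot flagged logical, per-bin monitor-status flag
#' @slot schedule the attached light schedule, or NULL
#' @export
setClass("ActivitySeries",
  representation(
    flyId    = "character",
    t0       = "POSIXctOrNULL",
    binMin   = "integer",
    counts   = "integer",
    flagged  = "logical",
    schedule = "LightScheduleOrNULL"
  )
)

setValidity("ActivitySeries", function(object) {
  msg <- character()
  if (length(object@flyId) != 1) msg <- c(msg, "flyId must be length 1")
  if (length(object@binMin) != 1 || object@binMin < 1L)
    msg <- c(msg, "binMin must be a positive integer")
  if (any(is.na(object@counts)) || any(object@counts < 0L))
    msg <- c(msg, "counts must be non-negative integers")
  if (length(object@flagged) != length(object@counts))
    msg <- c(msg, "flagged must parallel counts")
  if (!is.null(object@schedule)) {
    expect <- scheduleDurationMin(object@schedule) / object@binMin
    if (length(object@counts) != expect)
      msg <- c(msg, sprintf(
        "counts length %d does not match schedule duration (%d bins of %d min)",
        length(object@counts), as.integer(expect), object@binMin))
  }
  if (length(msg)) msg else TRUE
})

#' @param flyId fly identifier
#' @param counts integer beam-break counts per bin
#' @param schedule a \code{LightSchedule} (or NULL); when given, the series
#'   must cover the schedule exactly and is assumed to start at ZT0 of day 1
#' @param binMin minutes per bin
#' @param t0 absolute time of the first bin start; defaults to a nominal date
#'   at the schedule's lights-on clock time
#' @param flagged optional logical vector of per-bin status flags
#' @return an \code{ActivitySeries}
#' @rdname ActivitySeries-class
#' @export
activitySeries <- function(flyId, counts, schedule = NULL, binMin = 5L,
                           t0 = NULL, flagged = NULL) {
  counts <- as.integer(counts)
  if (is.null(flagged)) flagged <- rep(FALSE, length(counts))
  if (is.null(t0) && !is.null(schedule)) {
    t0 <- as.POSIXct("2024-01-01 00:00:00", tz = "UTC") +
      schedule@lightsOnClock * 3600
  }
  new("ActivitySeries", flyId = as.character(flyId), t0 = t0,
      binMin = as.integer(binMin), counts = counts,
      flagged = as.logical(flagged), schedule = schedule)
}

#' Single-fly bioluminescence trace
#'
#' A luciferase reporter time series for one living fly, sampled roughly once
#' per hour.  \code{alive} records whether the fly survived the assay; group
#' statistics use only alive flies.  \code{detrended} holds the linear-decay
#' corrected values once \code{\link{detrendTrace}} has run, and \code{fit}
#' the cosinor fit once \code{\link{cosinorFit}} has run.
#'
#' @slot flyId character identifier
#' @slot timesH sampling times in hours from recording start, strictly increasing
#' @slot values raw luminescence readings
#' @slot alive logical survival flag
#' @slot detrended detrended values (length 0 until detrending)
#' @slot fit cosinor fit parameters (empty list until fitted)
#' @export
setClass("LuciferaseTrace",
  representation(
    flyId     = "character",
    timesH    = "numeric",
    values    = "numeric",
    alive     = "logical",
    detrended = "numeric",
    fit       = "list"
  )
)

setValidity("LuciferaseTrace", function(object) {
  msg <- character()
  if (length(object@timesH) != length(object@values))
    msg <- c(msg, "timesH and values must have equal length")
  if (length(object@timesH) > 1 && any(diff(object@timesH) <= 0))
    msg <- c(msg, "timesH must be strictly increasing")
  if (length(object@detrended) &&
      length(object@detrended) != length(object@values))
    msg <- c(msg, "detrended must be empty or parallel values")
  if (length(object@alive) != 1) msg <- c(msg, "alive must be length 1")
  if (length(msg)) msg else TRUE
})

#' @param flyId fly identifier
#' @param timesH sampling times (hours from start)
#' @param values luminescence readings
#' @param alive survival flag (default TRUE)
#' @return a \code{LuciferaseTrace}
#' @rdname LuciferaseTrace-class
#' @export
luciferaseTrace <- function(flyId, timesH, values, alive = TRUE) {
  new("LuciferaseTrace", flyId = as.character(flyId),
      timesH = as.numeric(timesH), values = as.numeric(values),
      alive = as.logical(alive), detrended = numeric(0), fit = list())
}

#' Survival cohort from vial counts
#'
#' Daily alive counts for a genotype cohort kept in vials, each started with
#' \code{n0} flies.  Row \code{d + 1} of \code{vials} is the count alive at
#' day \code{d} (day 0 = assay start); \code{NA} marks days on which a vial
#' was not counted (flies are typically counted every one or two days).
#'
#' @slot genotype cohort label
#' @slot vials integer matrix, (horizonD + 1) rows by one column per vial
#' @slot n0 initial flies per vial
#' @slot horizonD last day of observation (right-censoring boundary)
#' @export
setClass("SurvivalCohort",
  representation(
    genotype = "character",
    vials    = "matrix",
    n0       = "integer",
    horizonD = "integer"
  )
)

setValidity("SurvivalCohort", function(object) {
  msg <- character()
  v <- object@vials
  if (nrow(v) != object@horizonD + 1L)
    msg <- c(msg, "vials must have horizonD + 1 rows (days 0..horizonD)")
  if (any(is.na(v[1L, ])) || any(v[1L, ] != object@n0))
    msg <- c(msg, "alive count at day 0 must equal n0 in every vial")
  for (j in seq_len(ncol(v))) {
    obs <- v[!is.na(v[, j]), j]
    if (any(diff(obs) > 0)) {
      d <- which(!is.na(v[, j]))[which(diff(obs) > 0)[1L] + 1L] - 1L
      msg <- c(msg, sprintf(
        "alive count increases in vial %d at day %d", j, d))
    }
  }
  if (length(msg)) msg else TRUE
})

#' @param vials matrix of alive counts (rows = days 0..horizonD, cols = vials)
#' @param genotype cohort label
#' @param n0 initial flies per vial (default: day-0 counts)
#' @return a \code{SurvivalCohort}
#' @rdname SurvivalCohort-class
#' @export
survivalCohort <- function(vials, genotype = "cohort", n0 = NULL) {
  vials <- as.matrix(vials)
  storage.mode(vials) <- "integer"
  if (is.null(n0)) n0 <- vials[1L, 1L]
  new("SurvivalCohort", genotype = as.character(genotype), vials = vials,
      n0 = as.integer(n0), horizonD = nrow(vials) - 1L)
}

#' Two-genotype, two-timepoint expression study
#'
#' A genes x samples log2 expression matrix with its sample factors, stored
#' as a \code{SummarizedExperiment}.  Samples belong to one cell of the
#' genotype (mutant / control) by timepoint (ZT3 / ZT15) design.  The
#' \code{floor} slot carries the log2 expression floor used by
#' \code{\link{filterExpressed}} (a gene is expressed when every sample of at
#' least one genotype group exceeds it).
#'
#' @slot floor log2 expression floor (default 4.0)
#' @export
setClass("ExpressionStudy",
  contains = "SummarizedExperiment",
  representation(floor = "numeric")
)

setValidity("ExpressionStudy", function(object) {
  msg <- character()
  cd <- SummarizedExperiment::colData(object)
  need <- c("genotype", "timepoint")
  if (!all(need %in% colnames(cd)))
    return("colData must contain 'genotype' and 'timepoint'")
  if (!all(cd$genotype %in% c("mutant", "control")))
    msg <- c(msg, "genotype must be 'mutant' or 'control'")
  if (!all(cd$timepoint %in% c("ZT3", "ZT15")))
    msg <- c(msg, "timepoint must be 'ZT3' or 'ZT15'")
  if (length(object@floor) != 1 || !is.finite(object@floor))
    msg <- c(msg, "floor must be a single finite value")
  if (length(msg)) msg else TRUE
})

#' @param mat genes x samples matrix of log2 intensities, with rownames
#' @param samples data.frame with columns \code{sample}, \code{genotype}
#'   (mutant/control), \code{timepoint} (ZT3/ZT15) and optionally
#'   \code{replicate}; rows must match the matrix columns
#' @param floor log2 expression floor
#' @return an \code{ExpressionStudy}
#' @rdname ExpressionStudy-class
#' @export
expressionStudy <- function(mat, samples, floor = 4.0) {
  mat <- as.matrix(mat)
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("gene%05d", seq_len(nrow(mat)))
  if ("sample" %in% colnames(samples)) {
    if (!is.null(colnames(mat)) && !identical(colnames(mat), samples$sample))
      samples <- samples[match(colnames(mat), samples$sample), , drop = FALSE]
    if (anyNA(samples$sample))
      stop("sample sheet does not cover every matrix column")
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = mat),
    colData = S4Vectors::DataFrame(samples))
  new("ExpressionStudy", se, floor = as.numeric(floor))
}
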