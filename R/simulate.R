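#' Simulation specification constructors
#'
#' Validated parameter bundles for the synthetic-data generators.  The
#' defaults describe a "control-like" fly cohort: a 12:12 LD entrainment of 3
#' days followed by 7 days of free run, Poisson beam-break counts at a
#' baseline of 0.5 counts/min with a rectified-cosine circadian modulation,
#' a 4.5-fold masking multiplier during lights-on, and startle bursts after
#' light transitions.  Count magnitudes are calibration choices typical of
#' single-fly infrared monitors, not measured constants.
#'
#' @param nFlies number of flies
#' @param fractionRhythmic proportion of flies given a circadian rate
#'   component (the remainder are homogeneous Poisson)
#' @param periodH free-running period in hours
#' @param phaseH peak phase of the circadian component, hours after ZT0.
#'   The default 0 centres the (unimodal) activity peak on lights-on, the
#'   classic morning peak: the peak then straddles the dawn transition
#'   symmetrically, so the day/night activity ratio stays equal to the
#'   masking multiplier and the lights-off scoring window is not confounded
#'   by the circadian waveform
#' @param baselineRate expected counts per minute at rest
#' @param modulationDepth peak-to-mesor ratio of the rectified-cosine rate
#'   component (0 = arrhythmic shape)
#' @param dayMultiplier masking multiplier applied during lights-on bins of
#'   LD days
#' @param startleOn,startleOff extra expected counts added uniformly across
#'   the 10 minutes following each lights-on / lights-off event.  The
#'   default burst of 25 counts is sized so that a control-like cohort
#'   responds to lights-off despite the opposing masking drop (day-to-night
#'   rate change of about -17.5 counts per 10 min at the default masking
#'   multiplier), reproducing the high on/off responder fractions typical
#'   of sighted flies
#' @param binMin minutes per recording bin (1 or 5)
#' @param nDaysLD,nDaysDD days of light:dark cycling and of constant darkness
#' @param seed integer RNG seed
#' @return a validated spec list of class \code{ActivitySimSpec}
#' @export
activitySimSpec <- function(nFlies = 32L, fractionRhythmic = 1,
                            periodH = 24, phaseH = 0,
                            baselineRate = 0.5, modulationDepth = 3,
                            dayMultiplier = 4.5,
                            startleOn = 25, startleOff = 25,
                            binMin = 5L, nDaysLD = 3L, nDaysDD = 7L,
                            seed = 1L) {
  nFlies <- checkCount(nFlies, "nFlies")
  checkProportion(fractionRhythmic, "fractionRhythmic")
  if (periodH <= 0) stop("periodH must be positive")
  if (phaseH < 0 || phaseH >= periodH)
    stop("phaseH must lie in [0, periodH)")
  checkNonNeg(baselineRate, "baselineRate")
  checkNonNeg(modulationDepth, "modulationDepth")
  checkNonNeg(dayMultiplier, "dayMultiplier")
  checkNonNeg(startleOn, "startleOn")
  checkNonNeg(startleOff, "startleOff")
  if (!binMin %in% c(1L, 5L)) stop("binMin must be 1 or 5")
  structure(list(
    nFlies = nFlies, fractionRhythmic = fractionRhythmic,
    periodH = periodH, phaseH = phaseH, baselineRate = baselineRate,
    modulationDepth = modulationDepth, dayMultiplier = dayMultiplier,
    startleOn = startleOn, startleOff = startleOff,
    binMin = as.integer(binMin), nDaysLD = checkCount(nDaysLD, "nDaysLD", 0L),
    nDaysDD = checkCount(nDaysDD, "nDaysDD", 0L),
    seed = checkCount(seed, "seed", 0L)), class = "ActivitySimSpec")
}

#' @param mesor0 initial mean emission level (luminescence units)
#' @param decayPerH linear decay slope, units per hour
#' @param relAmplitude oscillation amplitude relative to the mesor, in [0, 1)
#' @param noiseSd Gaussian read noise sd (units)
#' @param sampleIntervalH hours between reads (default 1)
#' @param nDays recording length in days
#' @param levelScale multiplier for group-level emission differences
#' @rdname activitySimSpec
#' @export
luciferaseSimSpec <- function(nFlies = 16L, mesor0 = 1000,
                              decayPerH = 3, relAmplitude = 0.3,
                              periodH = 24, phaseH = 14, noiseSd = 20,
                              sampleIntervalH = 1, nDays = 7L,
                              levelScale = 1, seed = 1L) {
  nFlies <- checkCount(nFlies, "nFlies")
  if (relAmplitude < 0 || relAmplitude >= 1)
    stop("relAmplitude must lie in [0, 1)")
  checkNonNeg(decayPerH, "decayPerH")
  checkNonNeg(noiseSd, "noiseSd")
  if (periodH <= 0) stop("periodH must be positive")
  if (sampleIntervalH <= 0) stop("sampleIntervalH must be positive")
  if (levelScale <= 0) stop("levelScale must be positive")
  nDays <- checkCount(nDays, "nDays")
  if (mesor0 - decayPerH * nDays * 24 <= 0)
    stop("emission becomes non-positive within the recording: ",
         "reduce decayPerH or nDays")
  structure(list(
    nFlies = nFlies, mesor0 = mesor0, decayPerH = decayPerH,
    relAmplitude = relAmplitude, periodH = periodH, phaseH = phaseH,
    noiseSd = noiseSd, sampleIntervalH = sampleIntervalH,
    nDays = nDays, levelScale = levelScale,
    seed = checkCount(seed, "seed", 0L)), class = "LuciferaseSimSpec")
}

#' @param nVials number of vials in the cohort
#' @param fliesPerVial flies per vial at day 0 (default 20)
#' @param medianLifespanD target median lifespan in days
#' @param shape Weibull shape (larger = more synchronous deaths)
#' @param horizonD last observed day; flies alive past it are right-censored
#' @rdname activitySimSpec
#' @export
survivalSimSpec <- function(nVials = 3L, fliesPerVial = 20L,
                            medianLifespanD = 6, shape = 3,
                            horizonD = 30L, seed = 1L) {
  if (shape <= 0) stop("shape must be positive")
  if (medianLifespanD <= 0) stop("medianLifespanD must be positive")
  spec <- structure(list(
    nVials = checkCount(nVials, "nVials"),
    fliesPerVial = checkCount(fliesPerVial, "fliesPerVial"),
    medianLifespanD = medianLifespanD, shape = shape,
    horizonD = checkCount(horizonD, "horizonD"),
    seed = checkCount(seed, "seed", 0L)), class = "SurvivalSimSpec")
  if (medianLifespanD > horizonD)
    warning("median lifespan exceeds the horizon: curve will be heavily ",
            "censored")
  spec
}

#' @param nGenes number of genes
#' @param samplesPerCell replicates per genotype x timepoint cell
#' @param nUp,nDown planted differentially expressed genes (up / down in the
#'   mutant)
#' @param plantedLog2fc magnitude of the planted genotype effect (log2 units)
#' @param timeEffectSd sd of the per-gene timepoint effect (log2 units)
#' @param baselineMean,baselineSd log2 baseline distribution of expressed
#'   genes (truncated above the floor so expressed status is planted)
#' @param floorFraction proportion of genes planted below the expression
#'   floor (drawn from the non-DE genes)
#' @param refConcordance intended proportion of planted genes whose reference
#'   fold change is pushed outside the reference 99\% interval with matching
#'   sign (the realized fraction is capped near 1 - coverage of the universe,
#'   since the interval is empirical)
#' @rdname activitySimSpec
#' @export
expressionSimSpec <- function(nGenes = 5000L, samplesPerCell = 3L,
                              nUp = 100L, nDown = 50L, plantedLog2fc = 1,
                              timeEffectSd = 0.3, noiseSd = 0.25,
                              baselineMean = 7, baselineSd = 1.5,
                              floorFraction = 0.2, refConcordance = 0.8,
                              seed = 1L) {
  nGenes <- checkCount(nGenes, "nGenes")
  nUp <- checkCount(nUp, "nUp", 0L); nDown <- checkCount(nDown, "nDown", 0L)
  if (nUp + nDown > nGenes) stop("nUp + nDown must not exceed nGenes")
  samplesPerCell <- checkCount(samplesPerCell, "samplesPerCell")
  if (samplesPerCell < 2L)
    stop("samplesPerCell must be >= 2 (differential testing needs residual ",
         "degrees of freedom)")
  checkNonNeg(timeEffectSd, "timeEffectSd")
  checkNonNeg(noiseSd, "noiseSd")
  checkNonNeg(baselineSd, "baselineSd")
  checkProportion(floorFraction, "floorFraction")
  checkProportion(refConcordance, "refConcordance")
  if (floor(floorFraction * nGenes) > nGenes - nUp - nDown)
    stop("floorFraction leaves too few genes outside the planted DE sets")
  structure(list(
    nGenes = nGenes, samplesPerCell = samplesPerCell, nUp = nUp,
    nDown = nDown, plantedLog2fc = plantedLog2fc,
    timeEffectSd = timeEffectSd, noiseSd = noiseSd,
    baselineMean = baselineMean, baselineSd = baselineSd,
    floorFraction = floorFraction, refConcordance = refConcordance,
    seed = checkCount(seed, "seed", 0L)), class = "ExpressionSimSpec")
}

#' Simulate a cohort of DAM activity series with known truth
#'
#' Counts per bin are Poisson with rate
#' \code{baselineRate * binMin * (1 + modulationDepth *
#' max(0, cos(2*pi*(t - phaseH)/periodH)))} for rhythmic flies (bin
#' midpoints \code{t}, hours) and \code{baselineRate * binMin} for
#' arrhythmic flies, multiplied by \code{dayMultiplier} during lights-on
#' bins, plus startle mass spread uniformly over the 10 minutes after each
#' light transition.  A fixed seed gives bit-identical output.
#'
#' @param spec an \code{\link{activitySimSpec}}
#' @param schedule optional \code{\link{lightSchedule}}; defaults to one
#'   matching the spec's day counts.  Its duration must match the spec and
#'   its transitions must fall on bin boundaries.
#' @return list with \code{series} (list of \code{ActivitySeries}) and
#'   \code{truth} (data.frame: flyId, rhythmic, periodH, phaseH)
#' @export
simulateActivity <- function(spec, schedule = NULL) {
  stopifnot(inherits(spec, "ActivitySimSpec"))
  if (is.null(schedule))
    schedule <- lightSchedule(nDaysLD = spec$nDaysLD, nDaysDD = spec$nDaysDD)
  if (schedule@nDaysLD != spec$nDaysLD || schedule@nDaysDD != spec$nDaysDD)
    stop("schedule duration does not match the simulation spec")
  binMin <- spec$binMin
  tr <- lightTransitions(schedule)
  if (any(tr$timeMin %% binMin != 0))
    stop("schedule mismatch: light transitions do not fall on ",
         binMin, "-min bin boundaries")
  nBins <- scheduleDurationMin(schedule) / binMin
  midH <- ((seq_len(nBins) - 1) * binMin + binMin / 2) / 60
  onMask <- lightsOnMask(schedule, binMin)

  circad <- 1 + spec$modulationDepth *
    pmax(0, cos(2 * pi * (midH - spec$phaseH) / spec$periodH))
  mask <- ifelse(onMask, spec$dayMultiplier, 1)
  base <- spec$baselineRate * binMin

  # startle mass per bin: startle counts spread over the 10 post-event min
  startle <- numeric(nBins)
  startMin <- (seq_len(nBins) - 1) * binMin
  for (i in seq_len(nrow(tr))) {
    amt <- if (tr$kind[i] == "lights_on") spec$startleOn else spec$startleOff
    if (amt <= 0) next
    hit <- startMin >= tr$timeMin[i] & startMin < tr$timeMin[i] + 10
    startle[hit] <- startle[hit] + amt * binMin / 10
  }

  nRhythmic <- round(spec$fractionRhythmic * spec$nFlies)
  ids <- sprintf("fly%02d", seq_len(spec$nFlies))
  series <- withSeed(spec$seed, {
    lapply(seq_len(spec$nFlies), function(i) {
      lam <- if (i <= nRhythmic) base * circad else rep(base, nBins)
      lam <- lam * mask + startle
      activitySeries(ids[i], rpois(nBins, lam), schedule = schedule,
                     binMin = binMin)
    })
  })
  truth <- data.frame(
    flyId = ids,
    rhythmic = seq_len(spec$nFlies) <= nRhythmic,
    periodH = ifelse(seq_len(spec$nFlies) <= nRhythmic, spec$periodH, NA),
    phaseH = ifelse(seq_len(spec$nFlies) <= nRhythmic, spec$phaseH, NA))
  list(series = series, truth = truth)
}

#' Simulate bioluminescence reporter traces
#'
#' Trace value at time t (hours) is
#' \code{levelScale * (mesor0 - decayPerH * t) *
#' (1 + relAmplitude * cos(2*pi*(t - phaseH)/periodH))} plus Gaussian read
#' noise: a decaying oscillation emulating luciferin consumption over a
#' multi-day recording of a clock-driven transcriptional reporter.
#'
#' @param spec a \code{\link{luciferaseSimSpec}}
#' @return list with \code{traces} (list of \code{LuciferaseTrace}) and
#'   \code{truth} (data.frame of the planted parameters per fly)
#' @export
simulateLuciferase <- function(spec) {
  stopifnot(inherits(spec, "LuciferaseSimSpec"))
  timesH <- seq(0, spec$nDays * 24 - spec$sampleIntervalH,
                by = spec$sampleIntervalH)
  clean <- spec$levelScale * (spec$mesor0 - spec$decayPerH * timesH) *
    (1 + spec$relAmplitude *
       cos(2 * pi * (timesH - spec$phaseH) / spec$periodH))
  if (any(clean <= 0))
    stop("emission becomes non-positive within the recording")
  ids <- sprintf("fly%02d", seq_len(spec$nFlies))
  traces <- withSeed(spec$seed, {
    lapply(seq_len(spec$nFlies), function(i) {
      luciferaseTrace(ids[i], timesH,
                      clean + rnorm(length(timesH), 0, spec$noiseSd))
    })
  })
  truth <- data.frame(
    flyId = ids,
    mesor = spec$levelScale * (spec$mesor0 -
                                 spec$decayPerH * mean(timesH)),
    relAmplitude = spec$relAmplitude, periodH = spec$periodH,
    phaseH = spec$phaseH, levelScale = spec$levelScale)
  list(traces = traces, truth = truth)
}

#' Simulate a survival cohort with integer-day lifespans
#'
#' Lifespans are a discretized Weibull: \code{max(1, round(X))} with
#' \code{X ~ Weibull(shape, scale)} and the scale set so the continuous
#' median equals \code{medianLifespanD}.  In the large-shape limit every fly
#' dies on the median day.  Flies alive at \code{horizonD} are
#' right-censored.  Daily alive counts are tabulated per vial.
#'
#' @param spec a \code{\link{survivalSimSpec}}
#' @param genotype label for the cohort
#' @return list with \code{cohort} (a \code{SurvivalCohort}) and
#'   \code{truth} (data.frame: vial, fly, lifespanD, censored)
#' @export
simulateSurvival <- function(spec, genotype = "cohort") {
  stopifnot(inherits(spec, "SurvivalSimSpec"))
  n <- spec$nVials * spec$fliesPerVial
  scale <- spec$medianLifespanD / log(2)^(1 / spec$shape)
  life <- withSeed(spec$seed, {
    if (is.infinite(spec$shape)) rep(spec$medianLifespanD, n)
    else pmax(1, round(rweibull(n, shape = spec$shape, scale = scale)))
  })
  censored <- life > spec$horizonD
  vial <- rep(seq_len(spec$nVials), each = spec$fliesPerVial)
  days <- 0:spec$horizonD
  vials <- vapply(seq_len(spec$nVials), function(v) {
    lv <- life[vial == v]
    vapply(days, function(d) sum(lv > d), integer(1))
  }, integer(length(days)))
  list(
    cohort = survivalCohort(vials, genotype = genotype,
                            n0 = spec$fliesPerVial),
    truth = data.frame(vial = vial, fly = seq_len(n),
                       lifespanD = ifelse(censored, NA, life),
                       censored = censored))
}

#' Simulate a two-genotype, two-timepoint expression study
#'
#' Log2 values are gene baseline + genotype effect (plus/minus
#' \code{plantedLog2fc} on mutant samples of planted genes) + per-gene
#' timepoint effect + Gaussian noise.  A \code{floorFraction} of the non-DE
#' genes is planted strictly below the expression floor (baselines and time
#' effects bounded so the floored/expressed partition is deterministic at
#' zero noise).  A reference fold-change table over the whole gene universe
#' is built alongside: most genes draw from a null distribution, while an
#' intended \code{refConcordance} fraction of planted genes is pushed beyond
#' the null central 99\% range with the sign of their study effect.  Because
#' the published interval is an empirical quantile of the final table, at
#' most about 1\% of the universe can sit outside it, which caps the
#' realized outside fraction; the truth record stores the intention.
#'
#' @param spec an \code{\link{expressionSimSpec}}
#' @param floor log2 expression floor used for planting (default 4.0)
#' @return list with \code{study} (an \code{ExpressionStudy}),
#'   \code{truth} (per-gene data.frame) and \code{reference} (data.frame:
#'   gene, log2fc)
#' @export
simulateExpression <- function(spec, floor = 4.0) {
  stopifnot(inherits(spec, "ExpressionSimSpec"))
  g <- spec$nGenes
  genes <- sprintf("gene%05d", seq_len(g))
  dirn <- rep(0, g)
  if (spec$nUp > 0) dirn[seq_len(spec$nUp)] <- 1
  if (spec$nDown > 0) dirn[spec$nUp + seq_len(spec$nDown)] <- -1
  nFloor <- floor(spec$floorFraction * g)

  reps <- spec$samplesPerCell
  cells <- expand.grid(genotype = c("control", "mutant"),
                       timepoint = c("ZT3", "ZT15"),
                       stringsAsFactors = FALSE)
  samples <- data.frame(
    genotype = rep(cells$genotype, each = reps),
    timepoint = rep(cells$timepoint, each = reps),
    replicate = rep(seq_len(reps), times = nrow(cells)))
  samples$sample <- sprintf("%s_%s_r%d", samples$genotype,
                            samples$timepoint, samples$replicate)
  nS <- nrow(samples)

  out <- withSeed(spec$seed, {
    flooredIdx <- if (nFloor > 0)
      sample(which(dirn == 0), nFloor) else integer(0)
    floored <- seq_len(g) %in% flooredIdx

    baseline <- numeric(g)
    nExpr <- g - nFloor
    # truncated draws: expressed genes stay >= floor + 1, floored < floor - 1
    bl <- rnorm(nExpr, spec$baselineMean, spec$baselineSd)
    lo <- floor + 1
    bl[bl < lo] <- lo + abs(bl[bl < lo] - lo) %% 2
    baseline[!floored] <- bl
    if (nFloor > 0) baseline[floored] <- runif(nFloor, floor - 2.5, floor - 1)

    timeEff <- rnorm(g, 0, spec$timeEffectSd)
    timeEff <- pmin(pmax(timeEff, -0.9), 0.9)

    mat <- matrix(baseline, nrow = g, ncol = nS)
    isMut <- samples$genotype == "mutant"
    isZT15 <- samples$timepoint == "ZT15"
    mat[, isMut] <- mat[, isMut] + dirn * spec$plantedLog2fc
    mat[, isZT15] <- mat[, isZT15] + timeEff
    if (spec$noiseSd > 0)
      mat <- mat + matrix(rnorm(g * nS, 0, spec$noiseSd), nrow = g)

    refNullSd <- 0.5
    refFc <- rnorm(g, 0, refNullSd)
    nullHi <- qnorm(0.995, 0, refNullSd)
    plantedIdx <- which(dirn != 0)
    refOutside <- rep(FALSE, g)
    if (length(plantedIdx)) {
      conc <- runif(length(plantedIdx)) < spec$refConcordance
      outIdx <- plantedIdx[conc]
      refFc[outIdx] <- dirn[outIdx] *
        (nullHi + 0.2 + rexp(length(outIdx), 3))
      refOutside[outIdx] <- TRUE
    }
    list(mat = mat, floored = floored, timeEff = timeEff,
         refFc = refFc, refOutside = refOutside)
  })

  rownames(out$mat) <- genes
  colnames(out$mat) <- samples$sample
  study <- expressionStudy(out$mat, samples, floor = floor)
  truth <- data.frame(
    gene = genes,
    planted = c("none", "up", "down")[match(dirn, c(0, 1, -1))],
    log2fcTrue = dirn * spec$plantedLog2fc,
    timeEffect = out$timeEff,
    floored = out$floored,
    refOutsideIntended = out$refOutside)
  list(study = study, truth = truth,
       reference = data.frame(gene = genes, log2fc = out$refFc))
}

#' @importFrom stats qnorm rexp
NULL
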