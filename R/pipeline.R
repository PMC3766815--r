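# End-to-end orchestration: simulate (or load) each input class, run every
# analysis stage with the study's default thresholds, and emit per-group
# report tables plus a machine-readable manifest.  Stage seeds are derived
# from the master seed by stable hashing of stage names, so a fixed master
# seed gives byte-identical reports.

#' Study configuration for pipeline runs
#'
#' Bundles per-genotype simulation specs with the analysis parameters.  All
#' analysis defaults equal the study's standard values: RI threshold 0.2,
#' 10-min transition windows with responder threshold 2, log2 expression
#' floor 4.0, strict/lenient FDR cuts 0.05 / 0.15 at 1.5-fold, and a 99\%
#' reference interval.
#'
#' @param groups named list (one entry per genotype) of lists with elements
#'   \code{activity}, \code{luciferase}, \code{survival} (simulation specs;
#'   any may be NULL to skip that stage)
#' @param expression an \code{\link{expressionSimSpec}} or NULL
#' @param riThreshold,responderThreshold,transitionWindowMin,lastNDays
#'   behavioral-stage parameters (defaults as above)
#' @param exprFloor,strictQ,lenientQ,foldThreshold,intervalCoverage
#'   expression-stage parameters (defaults as above)
#' @param masterSeed master RNG seed; per-stage seeds are derived from it
#' @return a list of class \code{StudyConfig}
#' @export
studyConfig <- function(groups, expression = NULL,
                        riThreshold = 0.2, responderThreshold = 2,
                        transitionWindowMin = 10, lastNDays = 4,
                        exprFloor = 4.0, strictQ = 0.05, lenientQ = 0.15,
                        foldThreshold = 1.5, intervalCoverage = 0.99,
                        masterSeed = 1L) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list (one entry per genotype)")
  structure(list(groups = groups, expression = expression,
                 riThreshold = riThreshold,
                 responderThreshold = responderThreshold,
                 transitionWindowMin = transitionWindowMin,
                 lastNDays = lastNDays, exprFloor = exprFloor,
                 strictQ = strictQ, lenientQ = lenientQ,
                 foldThreshold = foldThreshold,
                 intervalCoverage = intervalCoverage,
                 masterSeed = as.integer(masterSeed)),
            class = "StudyConfig")
}

.reseedSpec <- function(spec, seed) {
  if (is.null(spec)) return(NULL)
  spec$seed <- seed
  spec
}

#' Run the behavioral arm of the study
#'
#' For every genotype group: simulates (or accepts) activity, luciferase
#' and survival inputs, then computes the cohort rhythm statistics
#' (percent rhythmic, mean RI, period distribution, RI histogram), the
#' light-transition responder fractions and amplitudes plus day/night
#' partition (from a 1-min LD recording simulated under the same group
#' parameters), the pooled survival curve and median lifespan with the
#' between-genotype Gehan-Breslow test, and the luciferase level ratio and
#' cosinor summaries.  Reports are returned and, when \code{outDir} is
#' given, written as CSV alongside a JSON manifest recording every
#' parameter, seed and exclusion.
#'
#' @param config a \code{\link{studyConfig}} with exactly the genotypes to
#'   compare (level comparisons use the first group as reference)
#' @param outDir optional output directory for report files
#' @return list of report tables: rhythm, riHistogram, periods,
#'   transitions, dayNight, survival, survivalTest, luciferase, manifest
#' @export
runBehaviorPipeline <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "StudyConfig"))
  gnames <- names(config$groups)
  ms <- config$masterSeed
  exclusions <- list()

  rhythmRows <- list(); riRows <- list(); periodRows <- list()
  transRows <- list(); dnRows <- list(); curves <- list()
  lucLevels <- list(); lucRows <- list(); cohorts <- list()

  for (g in gnames) {
    grp <- config$groups[[g]]

    if (!is.null(grp$activity)) {
      spec <- .reseedSpec(grp$activity, deriveSeed(ms, paste0("activity:", g)))
      sim <- simulateActivity(spec)
      dd <- lapply(sim$series, sliceDD)
      res <- analyzeRhythms(dd, threshold = config$riThreshold)
      exclusions[[paste0(g, ":rhythm")]] <-
        res$flyId[res$excluded]
      keep <- !res$excluded
      rhythmRows[[g]] <- data.frame(
        genotype = g, nFlies = nrow(res), nExcluded = sum(res$excluded),
        percentRhythmic = 100 * mean(res$rhythmic[keep]),
        meanRI = mean(res$RI[keep]),
        semRI = sd(res$RI[keep]) / sqrt(sum(keep)))
      hist <- riHistogram(res)
      riRows[[g]] <- data.frame(genotype = g, hist)
      per <- res$periodH[keep & res$rhythmic]
      periodRows[[g]] <- data.frame(
        genotype = g, nRhythmic = length(per),
        meanPeriodH = if (length(per)) mean(per) else NA_real_,
        sdPeriodH = if (length(per) > 1) sd(per) else NA_real_)

      # 1-min LD recording for transition scoring and day/night partition
      spec1 <- spec
      spec1$binMin <- 1L
      spec1$nDaysLD <- max(spec$nDaysLD, config$lastNDays + 1L)
      spec1$nDaysDD <- 0L
      spec1$seed <- deriveSeed(ms, paste0("activity1min:", g))
      sim1 <- simulateActivity(spec1)
      scores <- scoreAllTransitions(
        sim1$series, windowMin = config$transitionWindowMin,
        responderThreshold = config$responderThreshold)
      ts <- summarizeTransitions(scores, lastNDays = config$lastNDays)
      transRows[[g]] <- data.frame(genotype = g, ts)
      dn <- do.call(rbind, lapply(sim1$series, dayNightRatio))
      dnRows[[g]] <- data.frame(
        genotype = g, nFlies = nrow(dn),
        meanDayTotal = mean(dn$dayTotal),
        meanNightTotal = mean(dn$nightTotal),
        meanOverallTotal = mean(dn$overallTotal),
        meanRatio = mean(dn$ratio[dn$ratioDefined]),
        semRatio = sd(dn$ratio[dn$ratioDefined]) /
          sqrt(sum(dn$ratioDefined)))
    }

    if (!is.null(grp$survival)) {
      spec <- .reseedSpec(grp$survival, deriveSeed(ms, paste0("survival:", g)))
      simS <- simulateSurvival(spec, genotype = g)
      cohorts[[g]] <- simS$cohort
      cv <- buildSurvivalCurve(simS$cohort)
      curves[[g]] <- data.frame(genotype = g, cv$curve,
                                medianLifespanD = cv$medianLifespanD)
    }

    if (!is.null(grp$luciferase)) {
      spec <- .reseedSpec(grp$luciferase,
                          deriveSeed(ms, paste0("luciferase:", g)))
      simL <- simulateLuciferase(spec)
      traces <- markAlive(simL$traces)
      lucLevels[[g]] <- traces
      fits <- lapply(traces[vapply(traces, function(x) x@alive,
                                   logical(1))],
                     function(tr) cosinorFit(detrendTrace(tr)))
      lucRows[[g]] <- data.frame(
        genotype = g, nAlive = length(fits),
        meanLevel = mean(vapply(traces, function(tr) mean(tr@values),
                                numeric(1))),
        meanPeriodH = mean(vapply(fits, `[[`, numeric(1), "periodH")),
        meanRelAmplitude = mean(vapply(fits, `[[`, numeric(1),
                                       "relAmplitude")),
        meanAcrophaseH = mean(vapply(fits, `[[`, numeric(1),
                                     "acrophaseH")))
    }
  }

  survTest <- NULL
  if (length(cohorts) >= 2) {
    tst <- wilcoxonCurveTest(cohorts[[1]], cohorts[[2]])
    survTest <- data.frame(groupA = gnames[1], groupB = gnames[2],
                           statistic = tst$statistic, z = tst$z,
                           pValue = tst$pValue, method = tst$method)
  }
  lucCompare <- NULL
  if (length(lucLevels) >= 2) {
    cmp <- compareGroupLevels(lucLevels[[1]], lucLevels[[2]],
                              seed = deriveSeed(ms, "lucBootstrap"))
    lucCompare <- data.frame(groupA = gnames[1], groupB = gnames[2],
                             fractionalReduction = cmp$reduction,
                             ciLo = cmp$ciLo, ciHi = cmp$ciHi,
                             nA = cmp$nA, nB = cmp$nB)
  }

  manifest <- list(
    package = "circafly",
    version = as.character(utils::packageVersion("circafly")),
    masterSeed = ms,
    parameters = config[setdiff(names(config), c("groups", "expression"))],
    groups = lapply(config$groups, function(grp)
      lapply(grp, function(s) if (is.null(s)) NULL else unclass(s))),
    exclusions = exclusions)

  reports <- list(
    rhythm = do.call(rbind, rhythmRows),
    riHistogram = do.call(rbind, riRows),
    periods = do.call(rbind, periodRows),
    transitions = do.call(rbind, transRows),
    dayNight = do.call(rbind, dnRows),
    survival = do.call(rbind, curves),
    survivalTest = survTest,
    luciferase = do.call(rbind, lucRows),
    luciferaseComparison = lucCompare,
    manifest = manifest)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    for (nm in setdiff(names(reports), "manifest")) {
      if (is.null(reports[[nm]])) next
      df <- reports[[nm]]
      rownames(df) <- NULL
      write.csv(df, file.path(outDir, paste0(nm, ".csv")),
                row.names = FALSE)
    }
    writeTruthRecord(manifest, file.path(outDir, "manifest.json"))
  }
  reports
}

#' Run the expression arm of the study
#'
#' Simulates (or accepts) the expression matrix and reference table, runs
#' the floor filter, the timepoint-adjusted differential test, strict and
#' lenient signature selection, and the reference-interval overlap test;
#' when a truth record is present, scores the strict signature against the
#' planted genes as a confusion table.
#'
#' @param config a \code{\link{studyConfig}} whose \code{expression} slot is
#'   set
#' @param outDir optional output directory for report files
#' @return list: de (full table), summary, overlap, confusion, manifest
#' @export
runExpressionPipeline <- function(config, outDir = NULL) {
  stopifnot(inherits(config, "StudyConfig"))
  if (is.null(config$expression))
    stop("config has no expression simulation spec")
  ms <- config$masterSeed
  spec <- .reseedSpec(config$expression, deriveSeed(ms, "expression"))
  sim <- simulateExpression(spec, floor = config$exprFloor)
  de <- differentialExpression(sim$study)
  sel <- selectSignature(de, strictQ = config$strictQ,
                         lenientQ = config$lenientQ,
                         foldThreshold = config$foldThreshold)
  lenientGenes <- c(sel$lenientUp, sel$lenientDown)
  overlap <- NULL
  if (length(lenientGenes)) {
    sig <- data.frame(gene = lenientGenes,
                      log2fc = de$log2fc[match(lenientGenes, de$gene)])
    ov <- signatureOverlap(sig, sim$reference,
                           coverage = config$intervalCoverage,
                           seed = deriveSeed(ms, "overlap"))
    overlap <- data.frame(label = ov$label, intervalLo = ov$intervalLo,
                          intervalHi = ov$intervalHi,
                          nSignature = ov$nSignature,
                          nOutside = ov$nOutside,
                          nConcordant = ov$nConcordant,
                          permutationP = ov$permutationP)
  }
  truthPlanted <- sim$truth$planted != "none"
  strictGenes <- c(sel$strictUp, sel$strictDown)
  confusion <- data.frame(
    truePositive = sum(strictGenes %in% sim$truth$gene[truthPlanted]),
    falsePositive = sum(!strictGenes %in% sim$truth$gene[truthPlanted]),
    falseNegative = sum(truthPlanted) -
      sum(strictGenes %in% sim$truth$gene[truthPlanted]))
  summaryTab <- data.frame(
    nGenes = nrow(de), nExpressed = sum(de$expressed),
    nStrictUp = length(sel$strictUp), nStrictDown = length(sel$strictDown),
    nLenientUp = length(sel$lenientUp),
    nLenientDown = length(sel$lenientDown))
  manifest <- list(package = "circafly",
                   version = as.character(
                     utils::packageVersion("circafly")),
                   masterSeed = ms,
                   parameters = config[setdiff(names(config),
                                               c("groups", "expression"))],
                   expressionSpec = unclass(spec))
  reports <- list(de = sel$table, summary = summaryTab, overlap = overlap,
                  confusion = confusion, manifest = manifest)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(sel$table, file.path(outDir, "de_results.csv"),
              row.names = FALSE)
    write.csv(summaryTab, file.path(outDir, "de_summary.csv"),
              row.names = FALSE)
    if (!is.null(overlap))
      write.csv(overlap, file.path(outDir, "overlap.csv"),
                row.names = FALSE)
    write.csv(confusion, file.path(outDir, "confusion.csv"),
              row.names = FALSE)
    writeTruthRecord(manifest, file.path(outDir, "manifest.json"))
  }
  reports
}
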