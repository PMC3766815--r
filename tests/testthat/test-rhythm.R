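# Correlogram correctness against a brute-force oracle, RI semantics,
# histogram / actogram / profile contracts.

test_that("correlogram matches the direct double-summation oracle", {
  x <- c(0, 1, 2, 1, 0, 1, 2, 1, 0, 1, 2, 1)
  s <- activitySeries("f1", x, binMin = 60L)  # 1-h bins, lags in hours
  cg <- autocorrelogram(s, maxLagH = 4)
  expect_equal(cg$values, acfOracle(x, 4), tolerance = 1e-12)
  # period-4 pattern: perfect correlation at lag 4
  expect_equal(cg$values[5], max(cg$values[-1]))

  set.seed(21)
  for (rep in 1:5) {
    y <- rpois(240, 2)
    sy <- activitySeries(sprintf("r%d", rep), y, binMin = 60L)
    cgy <- autocorrelogram(sy, maxLagH = 60)
    expect_equal(cgy$values, acfOracle(y, 60), tolerance = 1e-10)
  }
})

test_that("correlogram flags zero variance and refuses short series", {
  s <- activitySeries("f1", rep(5L, 100), binMin = 60L)
  cg <- autocorrelogram(s, maxLagH = 10)
  expect_true(cg$zeroVariance)
  expect_equal(cg$values[1], 1)
  expect_true(all(is.na(cg$values[-1])))
  expect_error(autocorrelogram(s, maxLagH = 60), "reduce maxLag")
})

test_that("flagged bins are mean-imputed before the transform", {
  set.seed(3)
  x <- rpois(300, 3)
  fl <- rep(FALSE, 300); fl[c(10, 50)] <- TRUE
  s <- activitySeries("f1", x, binMin = 60L, flagged = fl)
  cg <- autocorrelogram(s, maxLagH = 20)
  expect_equal(cg$nImputed, 2)
  ximp <- as.numeric(x)
  ximp[fl] <- mean(x[!fl])
  expect_equal(cg$values, acfOracle(ximp, 20), tolerance = 1e-10)
})

test_that("noise-free 24-h cosine peaks at the circadian lag", {
  sch <- lightSchedule(nDaysLD = 0, nDaysDD = 7)
  s <- rateSeries(function(h) 50 * (1 + cos(2 * pi * h / 24)), sch)
  cg <- autocorrelogram(s, maxLagH = 30)
  win <- which(cg$lagsH >= 18 & cg$lagsH <= 30)
  peak <- cg$lags[win][which.max(cg$values[win])]
  # the biased (1/N) normalization tapers the correlogram, pulling the
  # finite-record peak at most a couple of bins below the true 288-bin lag
  expect_lte(abs(peak - 288), 2)
  expect_gt(cg$values[289], 0.4)  # strong correlation at the true lag
})

test_that("rhythmic call uses a strict RI threshold", {
  # engineered series whose window peak is the sinusoid's autocorrelation
  sch <- lightSchedule(nDaysLD = 0, nDaysDD = 7)
  s <- rateSeries(function(h) 50 * (1 + cos(2 * pi * h / 24)), sch)
  res <- analyzeRhythm(s)
  expect_gt(res$RI, 0.2)   # 0.25-like values are rhythmic
  expect_true(res$rhythmic)
  expect_lt(abs(res$periodH - 24), 0.25)
  # boundary: RI exactly at the threshold is NOT rhythmic
  resBoundary <- analyzeRhythm(s, threshold = res$RI)
  expect_false(resBoundary$rhythmic)
})

test_that("dead and over-flagged flies are excluded with reasons", {
  sch <- lightSchedule(nDaysLD = 0, nDaysDD = 7)
  nBins <- 2016L
  dead <- activitySeries("dead", c(rep(3L, nBins - 288L), rep(0L, 288L)),
                         schedule = sch, binMin = 5L)
  rd <- analyzeRhythm(dead)
  expect_true(rd$excluded)
  expect_match(rd$reason, "dead")
  expect_equal(rd$RI, 0)
  expect_false(rd$rhythmic)

  set.seed(2)
  flagged <- activitySeries("fl", rpois(nBins, 3), schedule = sch,
                            binMin = 5L,
                            flagged = runif(nBins) < 0.2)
  rf <- analyzeRhythm(flagged)
  expect_true(rf$excluded)
  expect_match(rf$reason, "flagged")

  const <- activitySeries("const", rep(2L, nBins), schedule = sch,
                          binMin = 5L)
  rc <- analyzeRhythm(const)
  expect_true(rc$excluded)
  expect_match(rc$reason, "zero-variance")
})

test_that("RI histogram is a relative-frequency table on [lo, hi) bins", {
  res <- data.frame(RI = c(0.05, 0.05, 0.05), excluded = FALSE)
  h <- riHistogram(res)
  expect_equal(sum(h$frequency), 1)
  expect_equal(h$frequency[h$lo == 0], 1)

  res2 <- data.frame(RI = c(0.05, 0.25), excluded = FALSE)
  h2 <- riHistogram(res2)
  expect_equal(h2$frequency[h2$lo == 0.0], 0.5)
  expect_equal(h2$frequency[abs(h2$lo - 0.2) < 1e-9], 0.5)

  # boundary value 0.1 belongs to the right bin (left-closed intervals)
  h3 <- riHistogram(data.frame(RI = 0.1, excluded = FALSE))
  expect_equal(h3$frequency[abs(h3$lo - 0.1) < 1e-9], 1)

  expect_error(riHistogram(data.frame(RI = 1, excluded = TRUE)),
               "excluded")
})

test_that("actogram matrix double-plots and conserves totals", {
  sch <- lightSchedule(nDaysLD = 0, nDaysDD = 2)
  set.seed(7)
  s <- activitySeries("f1", rpois(576, 2), schedule = sch, binMin = 5L)
  m <- actogramMatrix(s, doublePlot = TRUE)
  expect_equal(dim(m), c(2, 2 * 288))
  expect_true(all(is.na(m[2, 289:576])))  # last row half-padded
  # left halves hold the original days exactly
  expect_equal(as.numeric(t(m[, 1:288])), as.numeric(activityCounts(s)))
  mSingle <- actogramMatrix(s, doublePlot = FALSE)
  expect_equal(sum(mSingle), sum(activityCounts(s)))
})

test_that("25-h rhythm drifts +12 five-min bins per day on the actogram", {
  sch <- lightSchedule(nDaysLD = 0, nDaysDD = 8)
  # peak placed mid-day so its plateau never wraps a day boundary
  s25 <- rateSeries(function(h) 100 * (1 + cos(2 * pi * (h - 6) / 25)), sch)
  m <- actogramMatrix(s25, doublePlot = FALSE)
  peaks <- apply(m, 1, which.max)
  expect_true(all(diff(peaks) == 12))
  s24 <- rateSeries(function(h) 100 * (1 + cos(2 * pi * (h - 6) / 24)), sch)
  peaks24 <- apply(actogramMatrix(s24, doublePlot = FALSE), 1, which.max)
  expect_true(all(diff(peaks24) == 0))
})

test_that("average profile recovers a planted peak and flat signals", {
  sch <- lightSchedule(nDaysLD = 0, nDaysDD = 4)
  flat <- activitySeries("f1", rep(3L, 1152), schedule = sch, binMin = 5L)
  pf <- averageProfile(list(flat))
  expect_true(all(pf$mean == 3))

  # deterministic rectified cosine: folded profile peaks within one bin
  detSeries <- rateSeries(function(h)
    100 * (1 + 3 * pmax(0, cos(2 * pi * (h - 12) / 24))),
    lightSchedule(nDaysLD = 0, nDaysDD = 7))
  pfDet <- averageProfile(list(detSeries))
  # integer rounding flattens the crest into a short plateau; which.max
  # lands on its first bin, within a quarter hour of the planted phase
  expect_lte(abs(pfDet$timeH[which.max(pfDet$mean)] - 12), 0.25)
  expect_equal(max(pfDet$mean), 400)

  # Poisson cohort: peak within an hour of the planted phase
  spec <- activitySimSpec(nFlies = 12, nDaysLD = 0, nDaysDD = 7,
                          phaseH = 12, modulationDepth = 3,
                          baselineRate = 1, dayMultiplier = 1,
                          startleOn = 0, startleOff = 0, seed = 14)
  sim <- simulateActivity(spec)
  pf2 <- averageProfile(sim$series)
  peakH <- pf2$timeH[which.max(pf2$mean)]
  expect_lt(abs(peakH - 12), 1)

  expect_error(averageProfile(list()), "empty")
  s1 <- activitySeries("a", rep(1L, 288), binMin = 5L)
  s2 <- activitySeries("b", rep(1L, 1440), binMin = 1L)
  expect_error(averageProfile(list(s1, s2)), "mixed bin widths")
})
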