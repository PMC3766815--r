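# Light-transition scoring exactness, summarization, day/night partition.

makeMinuteSeries <- function(counts, nDaysLD = 1, nDaysDD = 0, id = "f1") {
  sch <- lightSchedule(nDaysLD = nDaysLD, nDaysDD = nDaysDD)
  activitySeries(id, counts, schedule = sch, binMin = 1L)
}

test_that("transition scoring reproduces the strict differential rule", {
  counts <- rep(0L, 1440)
  # lights-off at minute 720; pre window minutes 711..720, post 721..730
  counts[711:720] <- c(1L, 0L, 1L, 0L, 0L, 1L, 0L, 1L, 0L, 0L)  # pre = 4
  counts[721:730] <- c(1L, 1L, 1L, 0L, 1L, 1L, 0L, 1L, 1L, 0L)  # post = 7
  s <- makeMinuteSeries(counts)
  sc <- scoreTransition(s, 720, "lights_off")
  expect_equal(sc$preCounts, 4)
  expect_equal(sc$postCounts, 7)
  expect_equal(sc$differential, 3)
  expect_true(sc$responder)        # 3 > 2

  counts[711:720] <- 1L            # pre = 10
  counts[721:730] <- c(rep(1L, 10))
  counts[721:722] <- 2L            # post = 12
  sc2 <- scoreTransition(makeMinuteSeries(counts), 720, "lights_off")
  expect_equal(sc2$differential, 2)
  expect_false(sc2$responder)      # boundary: exactly 2 is not a response

  counts[721:730] <- counts[711:720]
  sc3 <- scoreTransition(makeMinuteSeries(counts), 720, "lights_off")
  expect_equal(sc3$differential, 0)
  expect_false(sc3$responder)
})

test_that("the bin at the event edge belongs to the post window", {
  counts <- rep(0L, 1440)
  counts[721] <- 5L   # minute index 721 = bin starting at the event edge
  sc <- scoreTransition(makeMinuteSeries(counts), 720, "lights_off")
  expect_equal(sc$postCounts, 5)
  expect_equal(sc$preCounts, 0)
})

test_that("scoring guards resolution, edges and flagged windows", {
  s5 <- activitySeries("f1", rep(0L, 288),
                       schedule = lightSchedule(nDaysLD = 1, nDaysDD = 0),
                       binMin = 5L)
  expect_error(scoreTransition(s5, 720, "lights_on"), "1-min")

  s <- makeMinuteSeries(rep(0L, 1440))
  sc <- scoreTransition(s, 0, "lights_on")   # no pre-window at start
  expect_false(sc$valid)
  expect_match(sc$reason, "truncated")

  fl <- rep(FALSE, 1440); fl[725] <- TRUE
  sf <- activitySeries("f1", rep(0L, 1440),
                       schedule = lightSchedule(nDaysLD = 1, nDaysDD = 0),
                       binMin = 1L, flagged = fl)
  scf <- scoreTransition(sf, 720, "lights_off")
  expect_false(scf$valid)
  expect_match(scf$reason, "flagged")
})

test_that("responder calls match an independent integer re-summation", {
  spec <- activitySimSpec(nFlies = 6, binMin = 1L, nDaysLD = 5,
                          nDaysDD = 0, startleOn = 5, startleOff = 3,
                          seed = 31)
  sim <- simulateActivity(spec)
  scores <- scoreAllTransitions(sim$series)
  for (i in seq_len(nrow(scores))) {
    if (!scores$valid[i]) next
    s <- sim$series[[match(scores$flyId[i],
                           vapply(sim$series, flyId, ""))]]
    e <- scores$eventMin[i]
    pre <- sum(activityCounts(s)[(e - 9):(e + 0)])
    post <- sum(activityCounts(s)[(e + 1):(e + 10)])
    expect_identical(scores$preCounts[i], pre)
    expect_identical(scores$postCounts[i], post)
    expect_identical(scores$responder[i], (post - pre) > 2L)
  }
})

test_that("cohort summary aggregates responders by majority rule", {
  # planted strong lights-on startle: everyone responds to lights-on
  spec <- activitySimSpec(nFlies = 12, binMin = 1L, nDaysLD = 5,
                          nDaysDD = 0, startleOn = 25, startleOff = 0,
                          modulationDepth = 0, baselineRate = 0.2,
                          dayMultiplier = 1, seed = 17)
  sim <- simulateActivity(spec)
  scores <- scoreAllTransitions(sim$series)
  sm <- summarizeTransitions(scores, lastNDays = 4)
  on <- sm[sm$eventKind == "lights_on", ]
  off <- sm[sm$eventKind == "lights_off", ]
  expect_equal(on$responderFraction, 1)
  expect_gt(on$meanAmplitude, 15)
  # lights-off fraction is near the Poisson null rate, far below 1
  expect_lt(off$responderFraction, 0.6)
  expect_error(suppressWarnings(
    summarizeTransitions(scores[0, , drop = FALSE])))
})

test_that("null responder fraction matches a direct Monte-Carlo of the rates", {
  lam <- 0.3
  spec <- activitySimSpec(nFlies = 150, binMin = 1L, nDaysLD = 5,
                          nDaysDD = 0, startleOn = 0, startleOff = 0,
                          modulationDepth = 0, baselineRate = lam,
                          dayMultiplier = 1, seed = 23)
  sim <- simulateActivity(spec)
  scores <- scoreAllTransitions(sim$series)
  valid <- scores[scores$valid, ]
  obs <- mean(valid$responder)
  # oracle: P(Pois(10*lam) - Pois(10*lam) > 2) by direct simulation
  set.seed(99)
  nullDiff <- rpois(2e5, 10 * lam) - rpois(2e5, 10 * lam)
  expected <- mean(nullDiff > 2)
  se <- sqrt(expected * (1 - expected) / nrow(valid))
  expect_lt(abs(obs - expected), 4 * se)
})

test_that("day/night partition conserves totals and handles degeneracy", {
  counts <- rep(1L, 1440)
  s <- makeMinuteSeries(counts)
  dn <- dayNightRatio(s)
  expect_equal(dn$ratio, 1)
  expect_equal(dn$dayTotal + dn$nightTotal, dn$overallTotal)
  expect_equal(dn$overallTotal, sum(counts))

  dayOnly <- c(rep(2L, 720), rep(0L, 720))
  dn2 <- dayNightRatio(makeMinuteSeries(dayOnly))
  expect_false(dn2$ratioDefined)
  expect_true(is.na(dn2$ratio))

  sDD <- activitySeries("f1", rep(1L, 288),
                        schedule = lightSchedule(nDaysLD = 0, nDaysDD = 1),
                        binMin = 5L)
  expect_error(dayNightRatio(sDD), "LD day")
})

test_that("planted masking multiplier is recovered by the cohort ratio", {
  spec <- activitySimSpec(nFlies = 24, binMin = 1L, nDaysLD = 4,
                          nDaysDD = 0, modulationDepth = 0,
                          dayMultiplier = 4.5, startleOn = 0,
                          startleOff = 0, baselineRate = 0.5, seed = 41)
  sim <- simulateActivity(spec)
  dn <- do.call(rbind, lapply(sim$series, dayNightRatio))
  m <- mean(dn$ratio)
  sem <- sd(dn$ratio) / sqrt(nrow(dn))
  expect_lt(abs(m - 4.5), 3 * sem + 0.05)
})

test_that("responder fraction rises monotonically with startle size", {
  frac <- vapply(c(0, 3, 6), function(st) {
    spec <- activitySimSpec(nFlies = 40, binMin = 1L, nDaysLD = 5,
                            nDaysDD = 0, startleOn = st, startleOff = st,
                            modulationDepth = 0, baselineRate = 0.3,
                            dayMultiplier = 1, seed = 300 + st)
    sim <- simulateActivity(spec)
    sm <- summarizeTransitions(scoreAllTransitions(sim$series))
    mean(sm$responderFraction)
  }, numeric(1))
  expect_true(all(diff(frac) >= 0))
  expect_lt(frac[1], 0.5)
  expect_gt(frac[3], frac[1])
})
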