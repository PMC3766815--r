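# Cohort survival curves from vial counts and the Gehan-Breslow
# generalized Wilcoxon comparison (the early-difference-weighted curve
# test), with normal-approximation, Monte-Carlo and exact-enumeration
# p-values.

#' Per-fly event table from vial counts
#'
#' Reconstructs individual (day, event) pairs from daily alive counts:
#' deaths during an observation gap are assigned to the first unobserved day
#' of the gap (config: \code{gap = "midpoint"} assigns them to the gap
#' midpoint); flies alive at the horizon are right-censored there.
#'
#' @param cohort a \code{SurvivalCohort}
#' @param gap how to place deaths inside observation gaps: "first" (default)
#'   or "midpoint"
#' @return data.frame: day, event (1 death / 0 censored), vial
#' @export
survivalEvents <- function(cohort, gap = c("first", "midpoint")) {
  gap <- match.arg(gap)
  out <- list()
  for (j in seq_len(ncol(cohort@vials))) {
    col <- cohort@vials[, j]
    obsDays <- which(!is.na(col)) - 1L
    obs <- col[!is.na(col)]
    for (i in seq_along(obsDays)[-1]) {
      d <- obs[i - 1] - obs[i]
      if (d > 0) {
        day <- if (obsDays[i] - obsDays[i - 1] == 1L) obsDays[i]
        else switch(gap,
                    first = obsDays[i - 1] + 1L,
                    midpoint = as.integer(
                      ceiling((obsDays[i - 1] + obsDays[i]) / 2)))
        out[[length(out) + 1]] <- data.frame(
          day = rep(day, d), event = 1L, vial = j)
      }
    }
    alive <- obs[length(obs)]
    if (alive > 0)
      out[[length(out) + 1]] <- data.frame(
        day = rep(cohort@horizonD, alive), event = 0L, vial = j)
  }
  if (!length(out))
    return(data.frame(day = integer(0), event = integer(0),
                      vial = integer(0)))
  do.call(rbind, out)
}

#' Pooled survival curve of a cohort
#'
#' Pools vials and reports, per day, the surviving fraction (total alive /
#' total initial), deaths and number at risk, with unobserved days carried
#' forward as a step function.  The median lifespan is the first day at
#' which the surviving fraction drops to 0.5 or below; if the curve never
#' reaches 0.5 within the horizon the median is reported absent (NA), not
#' the horizon.
#'
#' @param cohort a \code{SurvivalCohort}
#' @param gap see \code{\link{survivalEvents}}
#' @return list of class \code{SurvivalCurve}: data.frame \code{curve}
#'   (day, atRisk, deaths, survivingFraction), \code{medianLifespanD},
#'   \code{n0Total}, \code{genotype}
#' @export
buildSurvivalCurve <- function(cohort, gap = "first") {
  ev <- survivalEvents(cohort, gap = gap)
  n0 <- cohort@n0 * ncol(cohort@vials)
  days <- 0:cohort@horizonD
  deaths <- vapply(days, function(d) sum(ev$day == d & ev$event == 1L),
                   integer(1))
  alive <- n0 - cumsum(deaths)
  atRisk <- n0 - c(0L, cumsum(deaths)[-length(deaths)])
  frac <- alive / n0
  med <- if (any(frac <= 0.5)) days[which(frac <= 0.5)[1]] else NA_integer_
  structure(list(curve = data.frame(day = days, atRisk = atRisk,
                                    deaths = deaths,
                                    survivingFraction = frac),
                 medianLifespanD = med, n0Total = n0,
                 genotype = cohort@genotype),
            class = "SurvivalCurve")
}

#' @export
print.SurvivalCurve <- function(x, ...) {
  cat(sprintf("SurvivalCurve '%s': %d flies, median lifespan %s d\n",
              x$genotype, x$n0Total,
              if (is.na(x$medianLifespanD)) "not reached" else
                x$medianLifespanD))
  invisible(x)
}

#' Median lifespan of a cohort
#' @inheritParams buildSurvivalCurve
#' @return median lifespan in days, or NA when not reached
#' @export
medianLifespan <- function(cohort, gap = "first") {
  buildSurvivalCurve(cohort, gap = gap)$medianLifespanD
}

# Gehan-Breslow statistic on pooled event tables: U = sum_j w_j (d1j - e1j)
# with w_j = n_j (number at risk), plus its hypergeometric variance.
gehanStatistic <- function(day, event, inA) {
  dt <- sort(unique(day[event == 1L]))
  U <- 0; V <- 0
  for (tj in dt) {
    atRisk <- day >= tj
    nj <- sum(atRisk); n1j <- sum(atRisk & inA)
    dj <- sum(day == tj & event == 1L)
    d1j <- sum(day == tj & event == 1L & inA)
    e1j <- dj * n1j / nj
    U <- U + nj * (d1j - e1j)
    if (nj > 1)
      V <- V + nj^2 * dj * (nj - dj) * n1j * (nj - n1j) /
        (nj^2 * (nj - 1))
  }
  c(U = U, V = V)
}

#' Gehan-Breslow generalized Wilcoxon test of two survival cohorts
#'
#' Compares the survival experience of two cohorts using the
#' number-at-risk-weighted log-rank family statistic (Gehan-Breslow), the
#' standard survival-curve Wilcoxon that emphasizes early differences.
#' Per-fly event days are reconstructed from the daily vial counts and
#' censored at the horizon.  The two-sided p-value comes from the normal
#' approximation, or from the permutation distribution of group labels
#' (\code{method = "permutation"}): exact enumeration of label assignments
#' when there are at most \code{enumLimit} of them, otherwise a seeded
#' Monte-Carlo sample.
#'
#' @param cohortA,cohortB \code{SurvivalCohort} objects on compatible grids
#' @param method "asymptotic" (default) or "permutation"
#' @param nPerm Monte-Carlo permutations when enumeration is infeasible
#' @param enumLimit largest number of label assignments enumerated exactly
#' @param seed RNG seed for Monte-Carlo permutation
#' @param gap see \code{\link{survivalEvents}}
#' @return list: statistic (U), z, pValue, method, exact (logical),
#'   nA, nB, pDefined
#' @export
wilcoxonCurveTest <- function(cohortA, cohortB,
                              method = c("asymptotic", "permutation"),
                              nPerm = 10000, enumLimit = 1e5, seed = 1,
                              gap = "first") {
  method <- match.arg(method)
  evA <- survivalEvents(cohortA, gap = gap)
  evB <- survivalEvents(cohortB, gap = gap)
  day <- c(evA$day, evB$day)
  event <- c(evA$event, evB$event)
  inA <- c(rep(TRUE, nrow(evA)), rep(FALSE, nrow(evB)))
  if (sum(event) == 0L) {
    warning("no events in either cohort: p-value undefined")
    return(list(statistic = 0, z = NA_real_, pValue = NA_real_,
                method = method, exact = FALSE, nA = nrow(evA),
                nB = nrow(evB), pDefined = FALSE))
  }
  obs <- gehanStatistic(day, event, inA)
  if (method == "asymptotic") {
    z <- if (obs["V"] > 0) obs["U"] / sqrt(obs["V"]) else 0
    p <- if (obs["V"] > 0) 2 * pnorm(-abs(z)) else 1
    return(list(statistic = unname(obs["U"]), z = unname(z),
                pValue = unname(p), method = "asymptotic", exact = FALSE,
                nA = nrow(evA), nB = nrow(evB), pDefined = TRUE))
  }
  n <- length(day); nA <- nrow(evA)
  nComb <- choose(n, nA)
  permU <- if (nComb <= enumLimit) {
    idx <- utils::combn(n, nA)
    apply(idx, 2, function(ii) {
      lab <- rep(FALSE, n); lab[ii] <- TRUE
      gehanStatistic(day, event, lab)["U"]
    })
  } else {
    withSeed(seed, vapply(seq_len(nPerm), function(i) {
      lab <- rep(FALSE, n); lab[sample.int(n, nA)] <- TRUE
      gehanStatistic(day, event, lab)["U"]
    }, numeric(1)))
  }
  exact <- nComb <= enumLimit
  tol <- 1e-9 * max(1, abs(obs["U"]))
  p <- if (exact) mean(abs(permU) >= abs(obs["U"]) - tol)
  else (1 + sum(abs(permU) >= abs(obs["U"]) - tol)) / (length(permU) + 1)
  list(statistic = unname(obs["U"]),
       z = unname(if (obs["V"] > 0) obs["U"] / sqrt(obs["V"]) else 0),
       pValue = unname(p), method = "permutation", exact = exact,
       nA = nrow(evA), nB = nrow(evB), pDefined = TRUE)
}

#' Paired signed-rank variant on daily surviving fractions
#'
#' Fidelity-auditing companion to \code{\link{wilcoxonCurveTest}}: a
#' Wilcoxon signed-rank test on the paired per-day surviving fractions of
#' the two pooled curves.  Reported for comparison only; the Gehan-Breslow
#' test is the primary curve comparison.
#'
#' @inheritParams wilcoxonCurveTest
#' @return list: statistic, pValue
#' @export
pairedFractionTest <- function(cohortA, cohortB, gap = "first") {
  cA <- buildSurvivalCurve(cohortA, gap = gap)$curve
  cB <- buildSurvivalCurve(cohortB, gap = gap)$curve
  n <- min(nrow(cA), nrow(cB))
  w <- suppressWarnings(
    stats::wilcox.test(cA$survivingFraction[seq_len(n)],
                       cB$survivingFraction[seq_len(n)],
                       paired = TRUE, exact = FALSE))
  list(statistic = unname(w$statistic), pValue = w$p.value)
}
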