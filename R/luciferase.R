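# Bioluminescence reporter analysis: linear-decay detrending, cosinor
# fitting over a period grid, and group emission-level comparison.

#' Remove the linear emission decay from a trace
#'
#' Fits an ordinary-least-squares line to (time, value) and subtracts it,
#' adding the original mean back so the trace mean is preserved exactly.
#' This removes the slow decay of emission (luciferin consumption) while
#' leaving the oscillatory component intact.  A divisive variant
#' (\code{method = "divisive"}: values divided by the fitted line, rescaled
#' to the original mean) is available for sensitivity checks.
#'
#' @param trace a \code{LuciferaseTrace} with at least 24 points spanning at
#'   least 48 h
#' @param method "subtractive" (default) or "divisive"
#' @return the trace with its \code{detrended} slot filled
#' @export
detrendTrace <- function(trace, method = c("subtractive", "divisive")) {
  method <- match.arg(method)
  t <- trace@timesH; y <- trace@values
  if (length(y) < 24 || diff(range(t)) < 48)
    stop("detrending needs >= 24 points spanning >= 48 h (got ",
         length(y), " points over ", round(diff(range(t)), 1), " h)")
  fitLine <- lm(y ~ t)
  line <- as.numeric(fitted(fitLine))
  trace@detrended <- switch(method,
    subtractive = y - line + mean(y),
    divisive = {
      if (any(line <= 0))
        stop("fitted decay line crosses zero: divisive detrending invalid")
      mean(y) * y / line
    })
  trace
}

#' Cosinor fit of a detrended trace over a period grid
#'
#' For each candidate period, solves the linear least-squares problem on the
#' basis \{1, cos(2*pi*t/P), sin(2*pi*t/P)\} and keeps the period with the
#' smallest residual sum of squares (smallest period on exact ties).
#' Amplitude and acrophase follow from the cosine/sine coefficients;
#' acrophase is reported in [0, period).
#'
#' @param trace a detrended \code{LuciferaseTrace} (see
#'   \code{\link{detrendTrace}}); an un-detrended trace is fit on its raw
#'   values
#' @param periodGridH candidate periods in hours (default 20 to 28 by 0.1)
#' @return list of class \code{CosinorFit}: mesor, amplitude, relAmplitude,
#'   acrophaseH, periodH, rss, degenerate
#' @export
cosinorFit <- function(trace, periodGridH = seq(20, 28, by = 0.1)) {
  if (!length(periodGridH)) stop("empty period grid")
  t <- trace@timesH
  y <- if (length(trace@detrended)) trace@detrended else trace@values
  best <- NULL
  for (P in periodGridH) {
    X <- cbind(1, cos(2 * pi * t / P), sin(2 * pi * t / P))
    b <- qr.coef(qr(X), y)
    rss <- sum((y - X %*% b)^2)
    if (is.null(best) || rss < best$rss - 1e-12)
      best <- list(b = b, rss = rss, P = P)
  }
  bc <- best$b[2]; bs <- best$b[3]
  amp <- sqrt(bc^2 + bs^2)
  # y = M + amp*cos(2*pi*(t - phi)/P)  =>  phi = P*atan2(bs, bc)/(2*pi)
  phi <- (best$P * atan2(bs, bc) / (2 * pi)) %% best$P
  degenerate <- var(y) < .Machine$double.eps * max(1, mean(y)^2)
  fit <- structure(list(mesor = unname(best$b[1]), amplitude = amp,
                        relAmplitude = if (best$b[1] != 0)
                          amp / best$b[1] else NA_real_,
                        acrophaseH = unname(phi), periodH = best$P,
                        rss = best$rss, degenerate = degenerate),
                   class = "CosinorFit")
  fit
}

#' @export
print.CosinorFit <- function(x, ...) {
  cat(sprintf(
    "CosinorFit: mesor %.3g, amplitude %.3g (rel %.3f), acrophase %.2f h, period %.1f h (rss %.3g)%s\n",
    x$mesor, x$amplitude, x$relAmplitude, x$acrophaseH, x$periodH, x$rss,
    if (x$degenerate) " [degenerate: constant input]" else ""))
  invisible(x)
}

#' Attach a cosinor fit to a trace
#'
#' Convenience wrapper storing \code{\link{cosinorFit}} output in the
#' trace's \code{fit} slot.
#'
#' @inheritParams cosinorFit
#' @return the trace with its \code{fit} slot filled
#' @export
fitTrace <- function(trace, periodGridH = seq(20, 28, by = 0.1)) {
  trace@fit <- unclass(cosinorFit(trace, periodGridH))
  trace
}

#' Mark traces alive or dead by end-of-assay emission
#'
#' A fly is considered to have survived the assay when its final-day mean
#' emission exceeds \code{threshold} times its first-day mean; only alive
#' flies enter group statistics.
#'
#' @param traces list of \code{LuciferaseTrace}
#' @param threshold fraction of first-day emission (default 0.05)
#' @return the list with \code{alive} slots set
#' @export
markAlive <- function(traces, threshold = 0.05) {
  lapply(traces, function(tr) {
    t <- tr@timesH
    first <- mean(tr@values[t < min(t) + 24])
    last <- mean(tr@values[t >= max(t) - 24])
    tr@alive <- isTRUE(last > threshold * first)
    tr
  })
}

#' Fractional emission-level difference between two groups
#'
#' Per-fly level is the mean raw (pre-detrend) emission of each alive fly;
#' the statistic is the fractional reduction \code{1 - mean(B) / mean(A)},
#' with a seeded nonparametric bootstrap CI over flies.
#'
#' @param groupA,groupB lists of \code{LuciferaseTrace} (reference group
#'   first, so a lower-emitting B gives a positive reduction)
#' @param nBoot bootstrap replicates (default 2000)
#' @param seed RNG seed for the bootstrap
#' @param conf confidence level (default 0.95)
#' @return list: reduction, ciLo, ciHi, nA, nB, nExcludedA, nExcludedB
#' @export
compareGroupLevels <- function(groupA, groupB, nBoot = 2000, seed = 1,
                               conf = 0.95) {
  lvl <- function(g) vapply(g, function(tr) mean(tr@values), numeric(1))
  aliveA <- Filter(function(tr) tr@alive, groupA)
  aliveB <- Filter(function(tr) tr@alive, groupB)
  if (length(aliveA) < 2 || length(aliveB) < 2)
    stop("need at least 2 alive flies per group")
  la <- lvl(aliveA); lb <- lvl(aliveB)
  red <- 1 - mean(lb) / mean(la)
  boots <- withSeed(seed, {
    vapply(seq_len(nBoot), function(i) {
      1 - mean(sample(lb, replace = TRUE)) /
        mean(sample(la, replace = TRUE))
    }, numeric(1))
  })
  alpha <- (1 - conf) / 2
  ci <- quantile(boots, c(alpha, 1 - alpha), names = FALSE)
  list(reduction = red, ciLo = ci[1], ciHi = ci[2],
       nA = length(aliveA), nB = length(aliveB),
       nExcludedA = length(groupA) - length(aliveA),
       nExcludedB = length(groupB) - length(aliveB))
}

#' @importFrom stats fitted
NULL
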