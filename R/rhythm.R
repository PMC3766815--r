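# Circadian rhythmicity from beam-break series: correlogram, rhythm index
# (RI), rhythmic/arrhythmic calls, period estimate, actograms and profiles.

#' Biased-normalization correlogram of an activity series
#'
#' Sample autocorrelation with the biased (1/N) covariance normalization:
#' \deqn{r_k = \sum_{t=1}^{N-k} (x_t - \bar x)(x_{t+k} - \bar x) /
#'       \sum_{t=1}^{N} (x_t - \bar x)^2 .}
#' Flagged bins are mean-imputed before the transform (the imputation count
#' is reported) because the autocorrelation requires a complete uniform
#' grid.  A zero-variance series is flagged rather than producing NaNs.
#'
#' @param series an \code{ActivitySeries}
#' @param maxLagH maximum lag in hours (default 30, covering the circadian
#'   search window)
#' @return list of class \code{Correlogram}: \code{lags} (bins 0..L),
#'   \code{lagsH}, \code{values}, \code{nBins}, \code{zeroVariance},
#'   \code{nImputed}
#' @export
autocorrelogram <- function(series, maxLagH = 30) {
  binMin <- series@binMin
  maxLag <- as.integer(round(maxLagH * 60 / binMin))
  x <- as.numeric(series@counts)
  n <- length(x)
  if (n < 2L * maxLag)
    stop("series too short (", n, " bins) for max lag ", maxLag,
         " bins; reduce maxLagH")
  nImputed <- sum(series@flagged)
  if (nImputed > 0) x[series@flagged] <- mean(x[!series@flagged])
  xc <- x - mean(x)
  denom <- sum(xc^2)
  lags <- 0:maxLag
  if (denom == 0) {
    values <- c(1, rep(NA_real_, maxLag))
    zeroVar <- TRUE
  } else {
    values <- vapply(lags, function(k) {
      if (k == 0) 1 else sum(xc[1:(n - k)] * xc[(k + 1):n]) / denom
    }, numeric(1))
    zeroVar <- FALSE
  }
  structure(list(lags = lags, lagsH = lags * binMin / 60, values = values,
                 nBins = n, binMin = binMin, zeroVariance = zeroVar,
                 nImputed = nImputed),
            class = "Correlogram")
}

#' @export
print.Correlogram <- function(x, ...) {
  cat(sprintf("Correlogram: %d lags (0..%.1f h) over %d bins%s%s\n",
              length(x$lags) - 1, max(x$lagsH), x$nBins,
              if (x$zeroVariance) " [zero variance]" else "",
              if (x$nImputed) sprintf(" [%d bins imputed]", x$nImputed)
              else ""))
  invisible(x)
}

#' Rhythm analysis of one fly
#'
#' Computes the rhythm index (RI): the maximum correlogram value over lags in
#' the circadian window (18-30 h by default), taking the smallest lag on
#' exact ties.  The fly is called rhythmic iff RI strictly exceeds the
#' threshold (default 0.2), and the period estimate is the peak lag.
#' Exclusions (with RI = 0 and rhythmic = FALSE): a dead fly (no counts in
#' the final 24 h of recording), more than 10\% flagged bins, or a
#' zero-variance series.
#'
#' @param series a DD-restricted \code{ActivitySeries} (see
#'   \code{\link{sliceDD}})
#' @param expectedPeriodH nominal period used only to size the default
#'   correlogram
#' @param windowH two-element numeric, the lag window (hours) searched for
#'   the RI peak
#' @param threshold RI above which (strictly) a fly is called rhythmic
#' @return one-row data.frame of class \code{RhythmResult}: flyId, RI,
#'   peakLagH, periodH, rhythmic, excluded, reason
#' @export
analyzeRhythm <- function(series, expectedPeriodH = 24,
                          windowH = c(18, 30), threshold = 0.2) {
  excludedRow <- function(reason) {
    data.frame(flyId = series@flyId, RI = 0, peakLagH = NA_real_,
               periodH = NA_real_, rhythmic = FALSE, excluded = TRUE,
               reason = reason, stringsAsFactors = FALSE)
  }
  binMin <- series@binMin
  n <- length(series@counts)
  lastDayBins <- min(n, 1440 %/% binMin)
  if (sum(series@counts[(n - lastDayBins + 1):n]) == 0L)
    return(excludedRow("dead (no counts in final 24 h)"))
  if (mean(series@flagged) > 0.10)
    return(excludedRow("more than 10% of bins flagged"))
  cg <- autocorrelogram(series, maxLagH = windowH[2])
  if (cg$zeroVariance)
    return(excludedRow("zero-variance series"))
  inWin <- cg$lagsH >= windowH[1] & cg$lagsH <= windowH[2]
  vals <- cg$values[inWin]
  lagsH <- cg$lagsH[inWin]
  best <- which(vals == max(vals))[1L]  # smallest lag wins exact ties
  ri <- vals[best]
  data.frame(flyId = series@flyId, RI = ri, peakLagH = lagsH[best],
             periodH = lagsH[best], rhythmic = ri > threshold,
             excluded = FALSE, reason = "", stringsAsFactors = FALSE)
}

#' Rhythm analysis of a cohort
#'
#' Applies \code{\link{analyzeRhythm}} fly by fly and stacks the results.
#'
#' @param seriesList list of DD-restricted \code{ActivitySeries}
#' @inheritParams analyzeRhythm
#' @return data.frame with one row per fly
#' @export
analyzeRhythms <- function(seriesList, expectedPeriodH = 24,
                           windowH = c(18, 30), threshold = 0.2) {
  do.call(rbind, lapply(seriesList, analyzeRhythm,
                        expectedPeriodH = expectedPeriodH,
                        windowH = windowH, threshold = threshold))
}

#' Relative-frequency histogram of rhythm indexes
#'
#' Bins the RIs of non-excluded flies into left-closed right-open intervals
#' of width \code{binWidth} and reports relative frequencies summing to 1
#' (the standard way cohort rhythm-strength distributions are displayed).
#'
#' @param results data.frame from \code{\link{analyzeRhythms}}
#' @param binWidth RI interval width (default 0.1)
#' @return data.frame: lo, hi, frequency
#' @export
riHistogram <- function(results, binWidth = 0.1) {
  ri <- results$RI[!results$excluded]
  if (!length(ri)) stop("all flies are excluded: no RI distribution")
  lo <- floor(min(ri, 0) / binWidth) * binWidth
  hi <- (floor(max(ri) / binWidth) + 1) * binWidth
  edges <- seq(lo, hi, by = binWidth)
  idx <- findInterval(ri, edges, rightmost.closed = FALSE)
  freq <- tabulate(idx, nbins = length(edges) - 1)
  data.frame(lo = edges[-length(edges)], hi = edges[-1],
             frequency = freq / length(ri))
}

#' Actogram matrix for raster plotting
#'
#' Lays a series out as one row per day.  With \code{doublePlot} each row
#' holds day d followed by day d+1 (the conventional double-plotted
#' actogram); the final row pads the missing next day with NA.
#'
#' @param series an \code{ActivitySeries} with at least one full day
#' @param doublePlot logical (default TRUE)
#' @return numeric matrix, days x bins-per-row
#' @export
actogramMatrix <- function(series, doublePlot = TRUE) {
  perDay <- 1440 %/% series@binMin
  nDays <- length(series@counts) %/% perDay
  if (nDays < 1) stop("need at least one full day of data")
  x <- as.numeric(series@counts[seq_len(nDays * perDay)])
  dayMat <- matrix(x, nrow = nDays, ncol = perDay, byrow = TRUE)
  if (!doublePlot) return(dayMat)
  m <- cbind(dayMat, rbind(dayMat[-1, , drop = FALSE],
                           rep(NA_real_, perDay)))
  rownames(m) <- paste0("day", seq_len(nDays))
  m
}

#' Average activity profile over the folded cycle
#'
#' Folds each fly's series modulo \code{foldPeriodH}, averages within fly
#' across cycles, then across flies, and reports the per-bin dispersion.
#'
#' @param seriesList list of \code{ActivitySeries} on identical bin widths
#' @param foldPeriodH folding period in hours (default 24)
#' @return data.frame: timeH (bin start within the cycle), mean, sd, sem, n
#' @export
averageProfile <- function(seriesList, foldPeriodH = 24) {
  if (!length(seriesList)) stop("empty series collection")
  binMin <- unique(vapply(seriesList, function(s) s@binMin, integer(1)))
  if (length(binMin) != 1)
    stop("mixed bin widths: re-bin to a common grid first")
  perCycle <- as.integer(round(foldPeriodH * 60 / binMin))
  flyMeans <- vapply(seriesList, function(s) {
    x <- as.numeric(s@counts)
    nC <- length(x) %/% perCycle
    if (nC < 1) stop("series '", s@flyId, "' shorter than one fold period")
    colMeans(matrix(x[seq_len(nC * perCycle)], nrow = nC, byrow = TRUE))
  }, numeric(perCycle))
  flyMeans <- matrix(flyMeans, nrow = perCycle)
  n <- ncol(flyMeans)
  mu <- rowMeans(flyMeans)
  sdv <- if (n > 1) apply(flyMeans, 1, sd) else rep(NA_real_, perCycle)
  data.frame(timeH = (seq_len(perCycle) - 1) * binMin / 60,
             mean = mu, sd = sdv, sem = sdv / sqrt(n), n = n)
}
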