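# Independent oracles and fixture builders used across the suite.

# direct O(N*L) double-summation autocorrelation (biased normalization)
acfOracle <- function(x, maxLag) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  vapply(0:maxLag, function(k) {
    s <- 0
    for (t in seq_len(n - k)) s <- s + xc[t] * xc[t + k]
    s / denom
  }, numeric(1))
}

# deterministic activity series from a rate function of hours -> counts,
# rounded; useful for noise-free signal-shape tests
rateSeries <- function(rateFun, schedule, binMin = 5L, flyId = "flyX") {
  nBins <- circafly::scheduleDurationMin(schedule) / binMin
  midH <- ((seq_len(nBins) - 1) * binMin + binMin / 2) / 60
  activitySeries(flyId, as.integer(round(rateFun(midH))),
                 schedule = schedule, binMin = binMin)
}

# type-7 quantile computed from first principles (sort + interpolate)
quantileOracle <- function(x, p) {
  xs <- sort(x)
  n <- length(xs)
  h <- (n - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

# balanced two-factor fixture study from an explicit genes x samples matrix
makeStudy <- function(mat, reps = ncol(mat) / 4, floor = 4) {
  samples <- data.frame(
    genotype = rep(rep(c("control", "mutant"), each = reps), 2),
    timepoint = rep(c("ZT3", "ZT15"), each = 2 * reps),
    replicate = rep(seq_len(reps), 4))
  samples$sample <- sprintf("%s_%s_r%d", samples$genotype,
                            samples$timepoint, samples$replicate)
  colnames(mat) <- samples$sample
  expressionStudy(mat, samples, floor = floor)
}
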