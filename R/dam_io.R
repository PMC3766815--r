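# Trikinetics DAM monitor file support.  Exactly one dialect is handled
# bit-exactly: the 42-column DAM System 3 layout (record index, date
# "DD Mon YY", time "HH:MM:SS", monitor status, five device fields, a
# light-sensor field, then 32 channel counts).  Other variants are rejected
# loudly rather than guessed at.

DAM_N_CHANNELS <- 32L
DAM_N_COLUMNS  <- 42L
DAM_STATUS_OK  <- 1L

.damMonths <- c("Jan", "Feb", "Mar", "Apr", "May", "Jun",
                "Jul", "Aug", "Sep", "Oct", "Nov", "Dec")

# locale-independent "DD Mon YY" + "HH:MM:SS" -> POSIXct (UTC)
.parseDamTimestamp <- function(date, time, lineNo) {
  dparts <- strsplit(date, " ", fixed = TRUE)
  bad <- lengths(dparts) != 3
  mon <- vapply(dparts, function(p) match(p[2], .damMonths), integer(1))
  bad <- bad | is.na(mon)
  if (any(bad))
    stop("unparseable date '", date[which(bad)[1]], "' at line ",
         lineNo[which(bad)[1]])
  day <- as.integer(vapply(dparts, `[`, "", 1))
  yy <- as.integer(vapply(dparts, `[`, "", 3))
  year <- ifelse(yy < 70, 2000L + yy, 1900L + yy)
  ts <- as.POSIXct(sprintf("%04d-%02d-%02d %s", year, mon, day, time),
                   tz = "UTC")
  if (anyNA(ts))
    stop("unparseable time '", time[which(is.na(ts))[1]], "' at line ",
         lineNo[which(is.na(ts))[1]])
  ts
}

#' Read a DAM System monitor file
#'
#' Parses the supported 42-column tab-separated dialect into one
#' \code{\linkS4class{ActivitySeries}} per channel.  Rows with a non-OK
#' monitor status are retained and their bins flagged on every channel, so
#' no reading is silently dropped.  The bin width is inferred from
#' consecutive timestamps and must be constant throughout the file.
#'
#' @param path file to read
#' @param schedule optional \code{\link{lightSchedule}} to attach to every
#'   series (its duration must then match the file)
#' @return list with \code{series} (32 \code{ActivitySeries}) and
#'   \code{meta} (binMin, t0, nReadings, nFlaggedRows)
#' @export
readDamMonitor <- function(path, schedule = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) stop("empty monitor file: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != DAM_N_COLUMNS))
    stop(sprintf(
      "parse error at line %d: expected %d tab-separated columns, found %d",
      which(nf != DAM_N_COLUMNS)[1], DAM_N_COLUMNS,
      nf[which(nf != DAM_N_COLUMNS)[1]]))
  m <- do.call(rbind, fields)
  ts <- .parseDamTimestamp(m[, 2], m[, 3], seq_along(lines))
  status <- suppressWarnings(as.integer(m[, 4]))
  counts <- suppressWarnings(
    matrix(as.integer(m[, 11:DAM_N_COLUMNS, drop = FALSE]),
           nrow = nrow(m)))
  if (anyNA(counts))
    stop("non-integer channel count at line ",
         which(rowSums(is.na(counts)) > 0)[1])
  if (nrow(m) > 1) {
    gaps <- as.numeric(diff(ts), units = "secs")
    if (length(unique(gaps)) != 1)
      stop("non-uniform timestamp spacing at line ",
           which(gaps != gaps[1])[1] + 1)
    binMin <- gaps[1] / 60
    if (binMin != round(binMin) || binMin < 1)
      stop("timestamp spacing is not a whole number of minutes")
  } else {
    binMin <- 1
  }
  flagged <- is.na(status) | status != DAM_STATUS_OK
  series <- lapply(seq_len(DAM_N_CHANNELS), function(ch) {
    activitySeries(sprintf("ch%02d", ch), counts[, ch],
                   schedule = schedule, binMin = as.integer(binMin),
                   t0 = ts[1], flagged = flagged)
  })
  list(series = series,
       meta = list(binMin = as.integer(binMin), t0 = ts[1],
                   nReadings = nrow(m), nFlaggedRows = sum(flagged)))
}

#' Write activity series as a DAM monitor file
#'
#' Emits the supported 42-column dialect.  Up to 32 series on identical
#' grids are written one channel each; unused channels are filled with
#' zeros.  A row's status is OK unless that bin is flagged in any series.
#'
#' @param series list of \code{ActivitySeries} (1 to 32, identical binMin,
#'   length and t0)
#' @param path output file
#' @return invisibly, the path
#' @export
writeDamMonitor <- function(series, path) {
  if (!length(series)) stop("no series to write")
  if (length(series) > DAM_N_CHANNELS)
    stop("at most ", DAM_N_CHANNELS, " channels per monitor file")
  binMin <- unique(vapply(series, function(s) s@binMin, integer(1)))
  if (length(binMin) != 1) stop("mixed bin widths: cannot write one file")
  nBins <- unique(vapply(series, function(s) length(s@counts), integer(1)))
  if (length(nBins) != 1) stop("series have different lengths")
  t0 <- series[[1]]@t0
  if (is.null(t0)) t0 <- as.POSIXct("2024-01-01 08:00:00", tz = "UTC")
  ts <- t0 + (seq_len(nBins) - 1) * binMin * 60
  lt <- as.POSIXlt(ts, tz = "UTC")
  date <- sprintf("%02d %s %02d", lt$mday, .damMonths[lt$mon + 1],
                  lt$year %% 100)
  time <- format(ts, "%H:%M:%S", tz = "UTC")
  counts <- matrix(0L, nrow = nBins, ncol = DAM_N_CHANNELS)
  flagged <- rep(FALSE, nBins)
  for (ch in seq_along(series)) {
    counts[, ch] <- series[[ch]]@counts
    flagged <- flagged | series[[ch]]@flagged
  }
  status <- ifelse(flagged, 51L, DAM_STATUS_OK)
  dev <- matrix(0L, nrow = nBins, ncol = 6L)  # 5 device fields + light sensor
  out <- cbind(seq_len(nBins), date, time, status, dev, counts)
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Re-bin an activity series to a coarser grid
#'
#' Sums counts within each new bin; downsampling only.  Total activity is
#' conserved exactly (integer arithmetic).  A new bin is flagged if any of
#' its source bins was flagged.
#'
#' @param series an \code{ActivitySeries}
#' @param newBinMin target bin width, an integer multiple of the current one
#' @return the re-binned \code{ActivitySeries}
#' @export
rebinSeries <- function(series, newBinMin) {
  newBinMin <- as.integer(newBinMin)
  if (newBinMin == series@binMin) return(series)
  if (newBinMin < series@binMin || newBinMin %% series@binMin != 0L)
    stop("newBinMin must be an integer multiple of the current bin width (",
         series@binMin, " min); upsampling is not possible")
  k <- newBinMin %/% series@binMin
  n <- length(series@counts)
  if (n %% k != 0L)
    stop("series length ", n, " is not divisible into ", newBinMin,
         "-min bins")
  grp <- rep(seq_len(n %/% k), each = k)
  newCounts <- as.integer(rowsum(series@counts, grp))
  newFlag <- as.logical(rowsum(as.integer(series@flagged), grp) > 0L)
  activitySeries(series@flyId, newCounts, schedule = series@schedule,
                 binMin = newBinMin, t0 = series@t0, flagged = newFlag)
}

#' Restrict a series to its constant-darkness days
#'
#' Returns only the bins after the final lights-off of the LD block, i.e.
#' the free-running portion on which rhythm analysis operates.  The attached
#' schedule is rewritten as all-DD.
#'
#' @param series an \code{ActivitySeries} with an attached schedule
#' @return the DD-only \code{ActivitySeries}
#' @export
sliceDD <- function(series) {
  sch <- series@schedule
  if (is.null(sch)) stop("series has no attached light schedule")
  if (sch@nDaysDD < 1L)
    stop("series has no constant-darkness days to slice")
  if (sch@nDaysLD == 0L) return(series)
  skipBins <- sch@nDaysLD * 1440 %/% series@binMin
  keep <- (skipBins + 1):length(series@counts)
  newSch <- lightSchedule(nDaysLD = 0L, nDaysDD = sch@nDaysDD,
                          photoperiodH = sch@photoperiodH,
                          lightsOnClock = sch@lightsOnClock)
  t0 <- if (is.null(series@t0)) NULL else series@t0 + skipBins *
    series@binMin * 60
  activitySeries(series@flyId, series@counts[keep], schedule = newSch,
                 binMin = series@binMin, t0 = t0,
                 flagged = series@flagged[keep])
}
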