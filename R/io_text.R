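# Plain-text interchange: luminescence and survival tables as CSV,
# expression matrix + sample sheet + reference table as TSV, truth records
# and run manifests as JSON.

#' Write / read luciferase traces as long-format CSV
#'
#' Columns: fly_id, time_h, value, alive.
#'
#' @param traces list of \code{LuciferaseTrace}
#' @param path CSV file
#' @return \code{writeLuciferaseCsv}: invisibly, the path;
#'   \code{readLuciferaseCsv}: list of \code{LuciferaseTrace}
#' @export
writeLuciferaseCsv <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(fly_id = tr@flyId, time_h = tr@timesH, value = tr@values,
               alive = tr@alive)
  }))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeLuciferaseCsv
#' @export
readLuciferaseCsv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  lapply(split(df, df$fly_id), function(d) {
    d <- d[order(d$time_h), , drop = FALSE]
    luciferaseTrace(d$fly_id[1], d$time_h, d$value, alive = d$alive[1])
  })
}

#' Write / read a survival cohort as CSV
#'
#' Columns: day, then one alive-count column per vial (NA = not counted).
#'
#' @param cohort a \code{SurvivalCohort}
#' @param path CSV file
#' @param genotype label used on re-read
#' @return \code{writeSurvivalCsv}: invisibly, the path;
#'   \code{readSurvivalCsv}: a \code{SurvivalCohort}
#' @export
writeSurvivalCsv <- function(cohort, path) {
  df <- data.frame(day = 0:cohort@horizonD, cohort@vials)
  colnames(df) <- c("day", paste0("vial", seq_len(ncol(cohort@vials))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeSurvivalCsv
#' @export
readSurvivalCsv <- function(path, genotype = "cohort") {
  df <- utils::read.csv(path)
  survivalCohort(as.matrix(df[, -1, drop = FALSE]), genotype = genotype)
}

#' Write / read an expression study as TSV matrix + sample sheet
#'
#' The matrix file has a \code{gene} column followed by one column per
#' sample; the sample sheet has columns sample, genotype, timepoint,
#' replicate.
#'
#' @param study an \code{ExpressionStudy}
#' @param matrixPath,samplesPath TSV files
#' @param floor log2 floor attached on re-read
#' @return \code{writeExpressionTsv}: invisibly, the matrix path;
#'   \code{readExpressionTsv}: an \code{ExpressionStudy}
#' @export
writeExpressionTsv <- function(study, matrixPath, samplesPath) {
  mat <- SummarizedExperiment::assay(study, "log2expr")
  df <- data.frame(gene = rownames(mat), mat, check.names = FALSE)
  write.table(df, matrixPath, sep = "\t", quote = FALSE, row.names = FALSE)
  cd <- as.data.frame(SummarizedExperiment::colData(study))
  write.table(cd, samplesPath, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(matrixPath)
}

#' @rdname writeExpressionTsv
#' @export
readExpressionTsv <- function(matrixPath, samplesPath, floor = 4.0) {
  df <- read.delim(matrixPath, check.names = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df$gene
  samples <- read.delim(samplesPath, stringsAsFactors = FALSE)
  expressionStudy(mat, samples, floor = floor)
}

#' Read a reference fold-change table (gene, log2fc) from TSV
#' @param path TSV with columns gene and log2fc
#' @return data.frame: gene, log2fc
#' @export
readReferenceTsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene", "log2fc") %in% colnames(df)))
    stop("reference table needs 'gene' and 'log2fc' columns")
  df[, c("gene", "log2fc")]
}

#' Write a truth record or run manifest as JSON
#' @param x a list or data.frame
#' @param path JSON file
#' @return invisibly, the path
#' @export
writeTruthRecord <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
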