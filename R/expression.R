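# Differential expression on a two-genotype x two-timepoint log2 matrix
# (expression floor filter, additive two-factor ANOVA with BH adjustment,
# fold-change signature selection) and cross-experiment signature overlap
# against a reference fold-change table via its central empirical interval.

#' Expression-floor filter
#'
#' A gene is expressed when every sample of at least one genotype group
#' strictly exceeds the study's log2 floor; genes expressed in neither
#' group are excluded from differential testing.
#'
#' @param study an \code{ExpressionStudy}
#' @return named logical vector, one flag per gene
#' @export
filterExpressed <- function(study) {
  mat <- SummarizedExperiment::assay(study, "log2expr")
  gt <- SummarizedExperiment::colData(study)$genotype
  fl <- study@floor
  allAbove <- function(cols) {
    apply(mat[, cols, drop = FALSE] > fl, 1, all)
  }
  out <- allAbove(gt == "mutant") | allAbove(gt == "control")
  names(out) <- rownames(mat)
  out
}

#' Per-gene differential expression, adjusted for time of day
#'
#' Fits the additive two-factor linear model (genotype + timepoint, no
#' interaction) to every expressed gene, takes the p-value from the F test
#' of the genotype term, reports the genotype effect (mutant minus control,
#' adjusted for timepoint) as the log2 fold change, and adjusts p-values by
#' Benjamini-Hochberg across the expressed genes only.  An interaction term
#' can be added (\code{interaction = TRUE}) for sensitivity analyses; the
#' genotype main-effect F test is reported either way.
#'
#' @param study an \code{ExpressionStudy} with >= 2 replicates per
#'   genotype x timepoint cell
#' @param interaction include a genotype:timepoint interaction in the fitted
#'   model (default FALSE)
#' @return data.frame: gene, log2fc, fStat, pValue, qValue, expressed --
#'   one row per gene of the study; statistics are NA for unexpressed genes
#' @export
differentialExpression <- function(study, interaction = FALSE) {
  mat <- SummarizedExperiment::assay(study, "log2expr")
  cd <- SummarizedExperiment::colData(study)
  cell <- table(cd$genotype, cd$timepoint)
  if (any(cell < 2L))
    stop("differential testing needs >= 2 replicates in every ",
         "genotype x timepoint cell")
  gt <- factor(cd$genotype, levels = c("control", "mutant"))
  tp <- factor(cd$timepoint, levels = c("ZT3", "ZT15"))
  X1 <- if (interaction) model.matrix(~ gt + tp + gt:tp)
        else model.matrix(~ gt + tp)
  X0 <- model.matrix(~ tp)
  n <- ncol(mat)
  df1 <- n - ncol(X1)
  if (df1 < 1L) stop("zero residual degrees of freedom")

  expressed <- filterExpressed(study)
  Y <- mat[expressed, , drop = FALSE]

  fitRss <- function(X, Y) {
    Q <- qr.Q(qr(X))
    H <- Q %*% t(Q)
    resid <- Y - Y %*% H        # Y rows = genes
    rowSums(resid^2)
  }
  rss1 <- fitRss(X1, Y)
  rss0 <- fitRss(X0, Y)
  # genotype coefficient = timepoint-adjusted mutant - control difference
  coefs <- t(qr.coef(qr(X1), t(Y)))
  log2fc <- coefs[, "gtmutant"]
  dfNum <- ncol(X1) - ncol(X0)
  # guard degenerate genes (no residual variation at floating-point scale):
  # no genotype improvement means F = 0, p = 1, never 0/0
  scale <- pmax(rowSums(Y * Y), 1)
  improve <- pmax(rss0 - rss1, 0)
  noImprove <- improve <= 1e-12 * scale
  f <- ifelse(rss1 > 1e-12 * scale,
              (improve / dfNum) / (rss1 / df1),
              ifelse(noImprove, 0, Inf))
  f[noImprove] <- 0
  p <- pf(f, dfNum, df1, lower.tail = FALSE)
  q <- p.adjust(p, method = "BH")

  out <- data.frame(gene = rownames(mat),
                    log2fc = NA_real_, fStat = NA_real_,
                    pValue = NA_real_, qValue = NA_real_,
                    expressed = expressed, stringsAsFactors = FALSE)
  idx <- match(rownames(Y), out$gene)
  out$log2fc[idx] <- log2fc
  out$fStat[idx] <- f
  out$pValue[idx] <- p
  out$qValue[idx] <- q
  rownames(out) <- NULL
  out
}

#' Select up/down signatures at strict and lenient thresholds
#'
#' The fold threshold is applied on the linear scale: a gene passes when
#' \code{|log2fc| > log2(foldThreshold)}.  The strict set uses the primary
#' FDR cut (q < 0.05 by default), the lenient set a relaxed one (q < 0.15),
#' so strict is nested in lenient.
#'
#' @param results data.frame from \code{\link{differentialExpression}}
#' @param strictQ,lenientQ FDR q-value cutoffs (strict < lenient)
#' @param foldThreshold linear fold-change threshold (default 1.5)
#' @return list: \code{table} (results plus selectedStrict /
#'   selectedLenient / direction columns), \code{strictUp},
#'   \code{strictDown}, \code{lenientUp}, \code{lenientDown} (gene vectors)
#' @export
selectSignature <- function(results, strictQ = 0.05, lenientQ = 0.15,
                            foldThreshold = 1.5) {
  lfcCut <- log2(foldThreshold)
  ok <- results$expressed & !is.na(results$qValue)
  passFold <- ok & abs(results$log2fc) > lfcCut
  strict <- passFold & results$qValue < strictQ
  lenient <- passFold & results$qValue < lenientQ
  dir <- ifelse(results$log2fc > 0, "up",
                ifelse(results$log2fc < 0, "down", "none"))
  dir[!ok] <- "none"
  tab <- results
  tab$selectedStrict <- strict
  tab$selectedLenient <- lenient
  tab$direction <- dir
  list(table = tab,
       strictUp = tab$gene[strict & dir == "up"],
       strictDown = tab$gene[strict & dir == "down"],
       lenientUp = tab$gene[lenient & dir == "up"],
       lenientDown = tab$gene[lenient & dir == "down"])
}

#' Central empirical interval of a reference fold-change table
#'
#' The interval containing \code{coverage} of the reference measurements:
#' lower bound at the (1 - coverage)/2 quantile, upper at the
#' 1 - (1 - coverage)/2 quantile, using the linear-interpolation quantile
#' convention (R type 7).
#'
#' @param refLog2fc numeric vector of reference log2 fold changes (>= 100
#'   values)
#' @param coverage central mass of the interval (default 0.99)
#' @return numeric c(lo, hi)
#' @export
referenceInterval <- function(refLog2fc, coverage = 0.99) {
  refLog2fc <- refLog2fc[is.finite(refLog2fc)]
  if (length(refLog2fc) < 100)
    stop("need at least 100 reference fold changes (got ",
         length(refLog2fc), ")")
  a <- (1 - coverage) / 2
  unname(quantile(refLog2fc, c(a, 1 - a), type = 7))
}

#' Signature overlap with a reference experiment
#'
#' Counts how many signature genes fall outside the reference experiment's
#' central empirical interval (\code{\link{referenceInterval}}) and, among
#' those, how many do so with a reference fold change whose sign matches
#' the study's fold change (concordant).  Significance of the concordant
#' count comes from a seeded permutation null: random gene sets of the same
#' size are drawn from the reference universe and scored against the
#' signature's own sign pattern, with
#' \code{p = (1 + #[null >= observed]) / (nPerm + 1)}.
#'
#' @param signature data.frame with columns \code{gene} and \code{log2fc}
#'   (the study's fold changes for the signature genes)
#' @param reference data.frame with columns \code{gene} and \code{log2fc}
#'   (the reference universe); signature genes missing from it are dropped
#'   with a message
#' @param coverage central interval mass (default 0.99)
#' @param nPerm number of permutations (default 10000)
#' @param seed RNG seed
#' @param label reference label carried into the result
#' @return list of class \code{SignatureOverlap}: intervalLo, intervalHi,
#'   nSignature, nOutside, nConcordant, permutationP, nDropped, seed, label
#' @export
signatureOverlap <- function(signature, reference, coverage = 0.99,
                             nPerm = 10000, seed = 1,
                             label = "reference") {
  m <- match(signature$gene, reference$gene)
  dropped <- sum(is.na(m))
  if (dropped > 0) {
    message(dropped, " signature gene(s) missing from the reference table ",
            "were dropped")
    signature <- signature[!is.na(m), , drop = FALSE]
    m <- m[!is.na(m)]
  }
  if (!nrow(signature))
    stop("empty signature after matching against the reference table")
  iv <- referenceInterval(reference$log2fc, coverage)
  refFc <- reference$log2fc[m]
  sgn <- sign(signature$log2fc)
  outside <- refFc < iv[1] | refFc > iv[2]
  concordant <- outside & sign(refFc) == sgn & sgn != 0
  nObs <- sum(concordant)

  nSig <- nrow(signature)
  uni <- reference$log2fc
  nullCounts <- withSeed(seed, {
    vapply(seq_len(nPerm), function(i) {
      fc <- uni[sample.int(length(uni), nSig)]
      out <- fc < iv[1] | fc > iv[2]
      sum(out & sign(fc) == sgn & sgn != 0)
    }, integer(1))
  })
  p <- (1 + sum(nullCounts >= nObs)) / (nPerm + 1)
  structure(list(label = label, intervalLo = iv[1], intervalHi = iv[2],
                 nSignature = nSig, nOutside = sum(outside),
                 nConcordant = nObs, permutationP = p,
                 nDropped = dropped, seed = seed),
            class = "SignatureOverlap")
}

#' @export
print.SignatureOverlap <- function(x, ...) {
  cat(sprintf(
    "SignatureOverlap vs '%s': %d/%d genes outside [%.3f, %.3f], %d sign-concordant (permutation p = %.4g)\n",
    x$label, x$nOutside, x$nSignature, x$intervalLo, x$intervalHi,
    x$nConcordant, x$permutationP))
  invisible(x)
}

#' @importFrom stats model.matrix
NULL
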