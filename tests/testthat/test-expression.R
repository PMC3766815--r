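# Floor filter semantics, timepoint-adjusted differential testing,
# signature thresholds, reference interval and overlap statistics.

test_that("floor filter implements the all-of-one-group quantifier", {
  mat <- rbind(
    g1 = c(4.1, 4.2, 4.3, 3.2, 3.1, 3.0, 4.4, 4.5, 4.1, 3.3, 3.2, 3.1),
    g2 = rep(3.9, 12),
    g3 = c(4.5, 3.9, 4.2, 4.6, 4.7, 4.8, 4.1, 4.2, 3.8, 3.9, 4.6, 4.4))
  # columns: control x3, mutant x3 (ZT3), control x3, mutant x3 (ZT15)
  study <- makeStudy(mat, reps = 3)
  ex <- filterExpressed(study)
  expect_true(ex[["g1"]])    # all control samples above 4.0
  expect_false(ex[["g2"]])   # nobody above
  expect_false(ex[["g3"]])   # both groups have a failing sample
})

test_that("floor filter agrees with brute-force all/any on random data", {
  set.seed(33)
  for (rep in 1:3) {
    mat <- matrix(rnorm(50 * 8, 4, 0.5), nrow = 50,
                  dimnames = list(sprintf("g%02d", 1:50), NULL))
    study <- makeStudy(mat, reps = 2)
    gt <- SummarizedExperiment::colData(study)$genotype
    brute <- apply(mat, 1, function(row)
      all(row[gt == "mutant"] > 4) || all(row[gt == "control"] > 4))
    expect_identical(unname(filterExpressed(study)), unname(brute))
  }
})

test_that("identical groups yield a null differential result", {
  mat <- matrix(5, nrow = 3, ncol = 12,
                dimnames = list(c("a", "b", "c"), NULL))
  de <- differentialExpression(makeStudy(mat, reps = 3))
  expect_equal(de$log2fc, rep(0, 3))
  expect_equal(de$fStat, rep(0, 3))
  expect_equal(de$pValue, rep(1, 3))
})

test_that("per-gene results match stats::aov with time-of-day adjustment", {
  set.seed(44)
  mat <- matrix(rnorm(5 * 12, 6, 1), nrow = 5,
                dimnames = list(sprintf("g%d", 1:5), NULL))
  study <- makeStudy(mat, reps = 3)
  de <- differentialExpression(study)
  cd <- as.data.frame(SummarizedExperiment::colData(study))
  gt <- factor(cd$genotype, levels = c("control", "mutant"))
  tp <- factor(cd$timepoint, levels = c("ZT3", "ZT15"))
  for (i in 1:5) {
    av <- summary(stats::aov(mat[i, ] ~ gt + tp))[[1]]
    expect_equal(de$fStat[i], av["gt", "F value"], tolerance = 1e-8)
    expect_equal(de$pValue[i], av["gt", "Pr(>F)"], tolerance = 1e-8)
    fit <- lm(mat[i, ] ~ gt + tp)
    expect_equal(de$log2fc[i], unname(coef(fit)["gtmutant"]),
                 tolerance = 1e-10)
  }
})

test_that("q-values are BH over expressed genes only and bound p", {
  spec <- expressionSimSpec(nGenes = 300, nUp = 10, nDown = 0,
                            floorFraction = 0.3, seed = 55)
  sim <- simulateExpression(spec)
  de <- differentialExpression(sim$study)
  expect_true(all(is.na(de$pValue[!de$expressed])))
  ok <- de$expressed
  expect_equal(de$qValue[ok],
               p.adjust(de$pValue[ok], method = "BH"))
  expect_true(all(de$qValue[ok] >= de$pValue[ok] - 1e-12))
})

test_that("planted high-signal genes are recovered with tight fold changes", {
  spec <- expressionSimSpec(nGenes = 800, nUp = 15, nDown = 10,
                            plantedLog2fc = 2, noiseSd = 0.1,
                            floorFraction = 0, seed = 66)
  sim <- simulateExpression(spec)
  de <- differentialExpression(sim$study)
  planted <- sim$truth$planted != "none"
  expect_true(all(abs(de$log2fc[planted] -
                        sim$truth$log2fcTrue[planted]) < 0.15))
  sel <- selectSignature(de)
  expect_setequal(c(sel$strictUp, sel$strictDown),
                  sim$truth$gene[planted])
  expect_setequal(sel$strictUp, sim$truth$gene[sim$truth$planted == "up"])
})

test_that("signature thresholds act on the linear fold scale and nest", {
  de <- data.frame(
    gene = c("a", "b", "c", "d"),
    log2fc = c(0.60, 2.0, 0.0, -0.7),
    fStat = 1, pValue = c(0.001, 0.02, 0.9, 0.001),
    qValue = c(0.03, 0.10, 0.95, 0.02),
    expressed = TRUE)
  sel <- selectSignature(de)
  expect_true("a" %in% sel$strictUp)      # 2^0.60 = 1.52 > 1.5, q 0.03
  expect_true("b" %in% sel$lenientUp)     # q 0.10: lenient only
  expect_false("b" %in% sel$strictUp)
  expect_false("c" %in% c(sel$lenientUp, sel$lenientDown))
  expect_true("d" %in% sel$strictDown)
  tab <- sel$table
  expect_true(all(!tab$selectedStrict | tab$selectedLenient))
})

test_that("reference interval matches a first-principles quantile oracle", {
  set.seed(77)
  x <- runif(200)
  iv <- referenceInterval(x, coverage = 0.99)
  expect_equal(iv[1], quantileOracle(x, 0.005), tolerance = 1e-12)
  expect_equal(iv[2], quantileOracle(x, 0.995), tolerance = 1e-12)
  expect_lt(abs(iv[1] - 0.005), 0.02)
  expect_lt(abs(iv[2] - 0.995), 0.02)

  # symmetric input: interval symmetric about the median
  y <- c(-rev(seq_len(500)), seq_len(500)) / 100
  ivy <- referenceInterval(y)
  expect_equal(ivy[1] + ivy[2], 2 * median(y), tolerance = 1e-10)

  expect_error(referenceInterval(rnorm(50)), "at least 100")
})

test_that("large-sample interval approaches the normal quantiles", {
  set.seed(88)
  x <- rnorm(10000)
  iv <- referenceInterval(x)
  expect_lt(abs(iv[1] + 2.576), 0.08)
  expect_lt(abs(iv[2] - 2.576), 0.08)
})

test_that("overlap statistic counts sign-concordant outliers", {
  set.seed(99)
  ref <- data.frame(gene = sprintf("g%04d", 1:2000),
                    log2fc = rnorm(2000, 0, 0.5))
  iv <- referenceInterval(ref$log2fc)
  # signature genes planted right outside the interval, signs matching
  sigGenes <- sprintf("g%04d", 1:20)
  ref$log2fc[1:10] <- iv[2] + 1.5 + (1:10) * 0.01
  ref$log2fc[11:20] <- iv[1] - 1.5 - (1:10) * 0.01
  sig <- data.frame(gene = sigGenes, log2fc = c(rep(1, 10), rep(-1, 10)))
  ov <- signatureOverlap(sig, ref, nPerm = 2000, seed = 5)
  expect_equal(ov$nOutside, 20)
  expect_equal(ov$nConcordant, ov$nOutside)
  expect_lt(ov$permutationP, 0.01)

  # signature at fold change zero: nothing outside, p near 1
  refNull <- data.frame(gene = ref$gene, log2fc = rnorm(2000, 0, 0.5))
  refNull$log2fc[1:20] <- 0
  ovNull <- signatureOverlap(sig, refNull, nPerm = 500, seed = 6)
  expect_equal(ovNull$nOutside, 0)
  expect_gt(ovNull$permutationP, 0.5)
})

test_that("overlap handles missing genes and empty signatures", {
  ref <- data.frame(gene = sprintf("g%04d", 1:200),
                    log2fc = rnorm(200))
  sig <- data.frame(gene = c("g0001", "nope1", "nope2"),
                    log2fc = c(1, 1, -1))
  expect_message(ov <- signatureOverlap(sig, ref, nPerm = 100, seed = 1),
                 "dropped")
  expect_equal(ov$nSignature, 1)
  expect_equal(ov$nDropped, 2)
  sigBad <- data.frame(gene = c("x", "y"), log2fc = c(1, -1))
  expect_error(suppressMessages(signatureOverlap(sigBad, ref)), "empty")
})

test_that("permutation p is reproducible under a fixed seed", {
  set.seed(101)
  ref <- data.frame(gene = sprintf("g%04d", 1:1000),
                    log2fc = rnorm(1000))
  sig <- data.frame(gene = sprintf("g%04d", 1:30),
                    log2fc = rnorm(30))
  p1 <- signatureOverlap(sig, ref, nPerm = 1000, seed = 9)$permutationP
  p2 <- signatureOverlap(sig, ref, nPerm = 1000, seed = 9)$permutationP
  expect_identical(p1, p2)
  expect_true(p1 > 0 && p1 <= 1)
})
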