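# circafly

Behavioral and molecular phenotyping of *Drosophila* disease models that
are read out through the circadian system — the analysis stack used when a
genetic lesion is restricted to clock-bearing tissues and the disease is
followed in living flies through locomotor rhythms, light-driven behavior,
a bioluminescent transcription reporter, lifespan, and head-transcriptome
signatures.

## What it computes

**Locomotor rhythmicity.** Beam-break counts from Trikinetics DAM monitors
(5-min bins, LD entrainment followed by constant darkness) are scored per
fly by the rhythm index

RI = max over lags τ ∈ [18 h, 30 h] of r(τ),  r(τ) = Σ (x_t − x̄)(x_{t+τ} − x̄) / Σ (x_t − x̄)²

the height of the correlogram peak in the circadian lag window (biased 1/N
normalization). A fly is rhythmic when RI > 0.2 (strict), and its
free-running period is the peak lag. Actograms, folded activity profiles
and RI histograms summarize cohorts.

**Light-transition responses.** From 1-min recordings, each lights-on /
lights-off event is scored by the differential
`post − pre` of total counts in the 10 min after vs before the event; a
fly responds when the differential exceeds 2 counts (strict). Day/night
activity totals and their ratio quantify masking.

**Reporter rhythms.** Per-fly luciferase traces are detrended by OLS
(removing the linear emission decay, mean preserved), cosinor-fitted over a
20–28 h period grid (least squares on {1, cos, sin}; amplitude
√(βc² + βs²), acrophase from atan2), and group emission levels compared as
the fractional reduction 1 − mean_B/mean_A with a bootstrap CI.

**Survival.** Vial counts become pooled survival curves with median
lifespan (first day at fraction ≤ 0.5); genotypes are compared with the
Gehan–Breslow generalized Wilcoxon U = Σ_j n_j (d_{1j} − e_{1j}), by normal
approximation or (exact) permutation.

**Expression.** A genes × samples log2 matrix over a two-genotype ×
two-timepoint (ZT3/ZT15) design is filtered at a log2 floor of 4.0 (all
samples of at least one genotype group must exceed it), tested per gene
with the additive ANOVA genotype + timepoint (F on genotype), BH-adjusted,
and thresholded at |fold| > 1.5 with q < 0.05 (strict) or q < 0.15
(lenient). Signatures are compared against a reference fold-change table
through its central 99% empirical interval, with a seeded permutation test
for sign-concordant outliers.

**Synthetic data.** `simulateActivity()`, `simulateLuciferase()`,
`simulateSurvival()` and `simulateExpression()` generate all of the above
with machine-readable planted truth, so every stage is verifiable without
animal recordings.

## Worked example

```r
library(circafly)

spec <- activitySimSpec(nFlies = 4, nDaysLD = 3, nDaysDD = 7, seed = 7)
sim  <- simulateActivity(spec)
res  <- analyzeRhythms(lapply(sim$series, sliceDD))
res[, c("flyId", "RI", "periodH", "rhythmic")]
#>   flyId        RI  periodH rhythmic
#> 1 fly01 0.5341541 24.00000     TRUE
#> 2 fly02 0.5743026 23.83333     TRUE
#> 3 fly03 0.5450578 23.91667     TRUE
#> 4 fly04 0.5512674 23.91667     TRUE
```

Each row is one fly: its rhythm index (all well above the 0.2 rhythmicity
threshold, as planted), the period estimated from the correlogram peak
(24 h planted; estimates within a few 5-min bins), and the resulting
rhythmic call. A survival comparison:

```r
a <- simulateSurvival(survivalSimSpec(medianLifespanD = 40, shape = 4,
                                      horizonD = 60, seed = 1))$cohort
b <- simulateSurvival(survivalSimSpec(medianLifespanD = 6, shape = 3,
                                      horizonD = 60, seed = 2))$cohort
medianLifespan(a); medianLifespan(b)
#> [1] 39
#> [1] 6
wilcoxonCurveTest(a, b)$pValue
#> [1] 1.058234e-26
```

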