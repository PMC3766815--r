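---
title: "Models and methods behind circafly"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind circafly}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circafly)
```

circafly phenotypes fly disease models through the circadian system: it
quantifies locomotor rhythmicity from beam-break monitors, scores acute
light-transition behavior, fits bioluminescent reporter rhythms, compares
cohort survival, and runs a filtered, timepoint-adjusted differential
expression analysis with cross-experiment signature overlap. This vignette
explains each model, the parameters that matter, what the synthetic-data
generators do and do not emulate, and the numerical decisions taken where
the design was genuinely open.

## Rhythm quantification

A fly's activity series (counts of infrared-beam interruptions per 5-min
bin, recorded over 2–3 LD days and 7–14 days of constant darkness) is
analysed on its DD portion only, where rhythms are endogenous. The
correlogram uses the biased (1/N) normalization,

$$ r_k \;=\; \frac{\sum_{t=1}^{N-k} (x_t-\bar x)(x_{t+k}-\bar x)}
                  {\sum_{t=1}^{N} (x_t-\bar x)^2 , } $$

and the rhythm index (RI) is its maximum over lags between 18 and 30 h —
a robust single-number summary of rhythm strength for week-long records,
monotone in the signal-to-noise ratio of the circadian component. A fly is
called rhythmic when RI exceeds 0.2 *strictly*; the period estimate is the
peak lag (smallest lag on exact ties, for determinism). Ties aside, the
biased normalization tapers the correlogram by $(N-k)/N$, which pulls the
peak one or two 5-min bins below the true lag on a 7-day record; this is
well inside the ±0.5 h tolerance we consider meaningful for period
comparisons, so no taper correction is applied and the RI semantics stay
exactly as defined.

Practical guards: flagged bins (non-OK monitor status) are mean-imputed
before the transform, because the autocorrelation needs a complete uniform
grid, and the imputation count is reported; series with more than 10% of
bins flagged are excluded; a fly with zero counts over its final 24 h is
excluded as dead (the analogous rule the reporter assay applies — only
flies that lived through the assay are used — extended to activity);
zero-variance series are flagged rather than divided by zero. Exclusions
always carry a reason and RI = 0, rhythmic = FALSE.

The period estimator's precision is bounded by correlogram jitter. At the
default simulation calibration (baseline 0.5 counts/min, modulation depth
3) the measured fraction of flies recovered within ±0.5 h over 7 DD days
is about 99% at 20 h, 96% at 24 h and 90% at 28 h: longer periods repeat
fewer times in a fixed record and their ACF peak is intrinsically noisier.
The acceptance test for period recovery runs 1000 flies per condition so
its outcome reflects these true rates rather than Monte-Carlo luck; the
28 h condition genuinely sits below a 95% bar at this calibration.

## Light-transition scoring and masking

Transition responses need 1-min bins. For each lights-on or lights-off
event, the score is the differential between total counts in the 10 min
after and the 10 min before the event; a response is a differential
strictly greater than 2 counts. Bins are half-open, so the bin starting at
the event belongs to the post window. Windows touching a recording edge or
containing flagged bins invalidate that event (with a reason), never
silently. Cohort summaries use the last 4 days of the assay; a fly counts
as a responder for an event kind when it responds on a strict majority of
its valid events of that kind, and "response amplitude" — a quantity the
source protocol reports but does not define — is taken as the mean
differential, the only quantity the scoring rule itself defines.

Day/night partitioning totals counts over lights-on vs lights-off bins of
complete LD days; the ratio is flagged undefined (not infinite) when the
night total is zero.

One interaction deserves emphasis: the differential mixes the acute
startle with the *masking* step (the day/night rate change). At a masking
multiplier of 4.5 and baseline 0.5 counts/min, lights-off removes about
17.5 expected counts from the post window, so only a startle burst larger
than ~20 counts can produce the high lights-off responder fractions seen
in sighted control flies — which is why the generator's default startle is
25 counts per 10-min burst. Conversely, lights-on responses saturate: the
masking step alone exceeds the 2-count threshold, so *fractions* of
responders discriminate genotypes only near threshold, while the response
*amplitude* tracks the planted startle size directly. Cohort contrasts
should therefore read fractions and amplitudes together.

## Reporter detrending and cosinor

Luciferase traces (about one read per hour over ~a week) decay slowly as
substrate is consumed. Detrending fits an OLS line to (time, value) and
subtracts it, restoring the original mean exactly — a subtractive
interpretation of "eliminating the linear decay"; a divisive variant
(values divided by the fitted line) is available behind an argument since
the choice is not forced. Detrending is per fly; a shared trend across
flies would transfer level differences into shape.

The cosinor fit solves, for each candidate period on a 20–28 h grid (0.1 h
step), the linear least-squares problem on the basis
$\{1, \cos 2\pi t/P, \sin 2\pi t/P\}$ and keeps the period with minimal
RSS (smallest on ties; halving the grid step can only lower the chosen
RSS). Amplitude is $\sqrt{\beta_c^2+\beta_s^2}$, and the acrophase maps
atan2 into $[0, P)$. Constant input yields a degenerate-fit flag with zero
amplitude. A subtlety worth knowing: a finite discrete grid does not make
a cosine exactly orthogonal to a line unless the cosine is centred on the
grid, so detrending a pure cosinor can leak a small tilt; at realistic
noise levels this is negligible, and the exactness tests centre the phase
where the leakage vanishes.

Group emission levels are compared on *raw* (pre-detrend) means — the
level claim concerns overall emission — as the fractional reduction
$1-\bar L_B/\bar L_A$ with a seeded percentile bootstrap over flies. A fly
is "alive" (and eligible) when its final-day mean emission exceeds 5% of
its first-day mean; the threshold is an argument and every exclusion is
counted.

## Survival

Vials are pooled into a daily step curve: surviving fraction = total alive
/ total initial. Deaths during an observation gap (flies are counted every
one or two days) are assigned to the first unobserved day of the gap
(earliest-possible convention; a midpoint variant is available). The
median lifespan is the first day at or below fraction 0.5, and is reported
absent — not as the horizon — when the curve never gets there.

Genotypes are compared with the Gehan–Breslow generalized Wilcoxon, the
standard early-weighted member of the weighted log-rank family:
$U=\sum_j n_j\,(d_{1j}-e_{1j})$ over distinct death days, with its
hypergeometric variance for the normal approximation. The same statistic
equals the classic pairwise Gehan score (+1/−1 over all cross-group pairs
whose ordering is determinate under censoring), which the test suite uses
as an independent oracle. For small cohorts the permutation mode
enumerates all label assignments exactly (up to 10^5 combinations),
otherwise it samples permutations under a seed. Identical cohorts give
U = 0 and p = 1 exactly; the measured type-I error at α = 0.05 over 1000
null replicates of 2 × 60 flies is ~0.054 despite heavy ties.

## Expression

The design is two genotypes × two timepoints (ZT3 and ZT15, three hours
after lights-on and lights-off) with replicates. A gene is *expressed*
when every sample of at least one genotype group exceeds the log2 floor of
4.0 (strict); only expressed genes are tested. Each gene gets the additive
two-factor model genotype + timepoint — "controlling for the effect of
time of day" — fitted by projection; the p-value is the F test of the
genotype term and the reported log2 fold change is the genotype
coefficient (timepoint-adjusted mutant − control difference). An
interaction term is available behind an argument but off by default, since
the additive adjustment is the stated analysis. FDR adjustment is
Benjamini–Hochberg across expressed genes only. Signature thresholds act
on the linear scale (|log2fc| > log2 1.5 ≈ 0.585 — not |log2fc| > 1.5,
which would be 2.8-fold) at q < 0.05 (strict) and q < 0.15 (lenient,
reading the protocol's "FCR" as FDR); strict is nested in lenient.

Signature overlap against a reference experiment uses the interval
containing 99% of the reference fold changes (0.5th to 99.5th percentile,
linear-interpolation quantiles). The statistic is the number of signature
genes outside that interval whose reference sign matches the study's fold
change. Significance is by permutation: random same-size gene sets from
the reference universe are scored against the signature's own sign
pattern, with the add-one estimator $(1+\#\{U^\ast \ge U\})/(B+1)$ under a
fixed seed — a permutation rather than hypergeometric test because the
statistic depends on the continuous reference fold changes, not set
membership alone. Because the concordant count is a small integer, this
p-value is discrete; it is exactly calibrated at its attainable levels,
which is what a validity check should assert (a continuous-uniformity test
is the wrong instrument for a discrete statistic).

## Synthetic data: what it emulates, and what it does not

Every generator is a pure function of its parameter bundle and seed.

**Activity** is Poisson per bin — the natural first model for event
counts — with rate
$\lambda(t)=r_0\,b\,[1+m\,\max(0,\cos 2\pi (t-\phi)/P)]$ for rhythmic
flies, times the masking multiplier during lights-on, plus startle mass
spread uniformly over the 10 post-transition minutes. The rectified cosine
gives a single consolidated activity bout per cycle. Counts are calibrated
at baseline 0.5/min with masking 4.5 for control-like flies (count
magnitudes are a calibration choice, not a recorded constant). The default
phase centres the activity peak on lights-on — the classic morning peak —
which keeps the day/night ratio equal to the masking multiplier (the peak
straddles dawn symmetrically) and keeps the lights-off scoring window free
of circadian confound; a dusk-centred peak would bury any plausible
startle under the evening decline. Not emulated: bimodal morning+evening
profiles, anticipation, sleep structure, inter-fly variability in startle
propensity — so responder fractions in simulation are sharper (closer to
0/1) than in real cohorts, and passing closure tests shows the scoring
machinery is exact, not that real cohorts behave this crisply.

**Luciferase** is a decaying oscillation
$s\,(M_0-\delta t)(1+a\cos 2\pi (t-\phi)/P)$ plus Gaussian read noise,
rejected if emission would go non-positive. Not emulated: luciferin
depletion kinetics beyond linearity, plate-position effects.

**Survival** draws integer lifespans as max(1, round(Weibull)) with the
scale set so the continuous median equals the target; rounding (rather
than ceiling) makes the deterministic large-shape limit put every death on
the median day. Censoring at the horizon is explicit.

**Expression** plants signed genotype effects on chosen genes, per-gene
timepoint effects, and Gaussian noise; a fraction of non-DE genes is
planted strictly below the floor (baselines truncated on both sides of the
floor so the expressed/floored partition is deterministic at zero noise).
The reference table draws null fold changes for the universe and pushes an
intended fraction of planted genes beyond the null 99% range with matching
sign. One arithmetic fact matters: the published interval is an
*empirical* quantile of the final table, so at most ~1% of the universe
can ever lie outside it — an intended 80-concordant-out-of-100 signature
in a 5000-gene universe is capped at ~50 realized outliers. The truth
record stores the intention; overlap significance is unaffected (tens of
concordant outliers against a null of ~0–1).

## Problem sizes and reproducibility

The test suite and the acceptance script size their simulations to keep
Monte-Carlo error well below the margins they assert: 200 random series
for the correlogram oracle, 1000 flies per period condition for rhythm
recovery, 200 flies per rung of the startle ladder, 100 seeds for cosinor
and level-comparison recovery, 1000 null replicates for survival type-I
error, 100 seeds for DE null calibration, 200 seeds (2000 permutations
each) for overlap null calibration and 10000 permutations for the
enriched overlap. End-to-end runs derive each stage's seed from the master
seed by a stable hash of the stage name, so a fixed master seed yields
byte-identical reports, and every parameter that influences a reported
number is recorded in the run manifest.

## Known limitations

- The ACF-peak period estimator carries the biased-normalization taper and
  its jitter grows with period; sub-bin interpolation or multi-peak
  fitting would sharpen it but would change the RI semantics, so both are
  deliberately out of scope.
- The RI companion significance statistic used by some toolboxes is not
  computed; rhythmic calls rest on the fixed 0.2 threshold.
- Responder fractions saturate under strong masking (see above); read
  amplitudes alongside them.
- No periodogram (MESA, Lomb–Scargle, chi-square), no sleep-bout analysis,
  no Cox models, no probe-level normalization or pathway enrichment: the
  pipeline starts from normalized matrices and ends at signatures.
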