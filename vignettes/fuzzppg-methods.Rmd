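---
title: "Fuzzy-inspired PPG risk modeling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Fuzzy-inspired PPG risk modeling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fuzzppg)
```

## The problem and the pipeline

Photoplethysmography (PPG) records blood-volume pulsations optically; its
waveform morphology and variability carry information about cardiovascular
health. `fuzzppg` implements a fuzzy-linguistic route from a raw
single-channel PPG record to a per-patient cardiovascular-disorder (CVD)
risk classification:

1. **Segmentation.** Each record (100 Hz by default) is cut into
   non-overlapping 2-second windows of 200 samples.
2. **Features.** Eight statistics per window: energy (raw sum of squares),
   unbiased variance and SD, approximate entropy (m = 2, r = 0.2·SD),
   mean, moment skewness, plain (non-excess) kurtosis, and the peak
   maximum.
3. **Fuzzy encoding.** Energy is the anchor input. Seven two-input Mamdani
   subsystems pair it with each remaining feature; each subsystem maps
   onto five triangular linguistic sets and fires a banded 13-rule
   associative matrix, emitting one of five output risk levels. The seven
   levels per segment become a seven-letter code word over `A..E`, valued
   by summing per-letter probabilities derived from five-bit positional
   weights (`A` = 1/31/7 ≈ 0.004608 up to `E` = 16/31/7 ≈ 0.073732).
4. **Optimization.** Each patient's code-word value stream is compressed
   toward a "singleton" pattern by one of four population metaheuristics
   (differential search, shuffled frog leaping, wolf search, animal
   migration), minimising a vector-quantization distortion.
5. **Classification.** The optimized length-375 vectors are framed into
   five 75-value instances per patient and classified by six classical
   classifiers under stratified 10-fold cross-validation, scored with the
   pipeline's bespoke metric formulas.

## Fuzzy system details

**Triangles from ranges.** The linguistic table gives only numeric ranges
per set. We place each triangle's apex at the range midpoint; the
outermost sets carry shoulders (Very Low is 1 below its peak, Very High is
1 above), so extreme inputs saturate rather than fall off the scale.

**Coverage gaps.** A few adjacent ranges do not touch (energy 0.1–0.7).
Rather than editing the printed ranges, a fallback assigns membership 1 to
the set whose support is nearest, with ties toward the higher set. This
keeps every finite input classifiable and the gap semantics explicit.

**One band, seven subsystems.** Only the energy-vs-variance rule grid is
published; whether the remaining six pairs used the same band is not
stated. We reuse the one banded grid for all seven subsystems by default
and expose the whole configuration (ranges and grid) as a YAML file
(`fuzzy_config_write()`), so any subsystem can be re-banded without code
changes.

**Inference and ties.** Conjunction is `min`, per-level aggregation `max`,
and the output is the argmax *label* (no crisp defuzzification — the
downstream encoding consumes letters). Ties break toward the higher risk
level, a deliberate safe-side choice. When no banded rule fires at all
(possible for discordant inputs, e.g. very low energy with very high
variance), the defined cell nearest the dominant input pair within the
energy row is used — documented, deterministic, and exercised by the
brute-force agreement test.

**Letter order.** A code word's seven positions follow the feature order
variance, ApEn, mean, SD, skewness, kurtosis, peak maximum. The source
material never fixes an order; only the value (an order-invariant sum) is
compared against printed examples.

**Canonical constants.** The per-letter probabilities are the printed
six-decimal truncations of `weight/7`, not the exact fractions, so worked
examples reproduce digit-for-digit (`EEDDCBE` → 0.322577). The two differ
by under 1e-5 per word, which a test pins down.

**Target codes.** The published example target (`EEEEDEE`) comes with no
construction rule. Our `target_code()` takes the position-wise modal
letter, ties toward higher risk. Applied to the published 60-word
two-minute CVD window this yields `BEEAEEE`, *not* `EEEEDEE`; the tally is
frozen in a test and the discrepancy is documented here rather than
patched — the original construction is simply unstated.

**Stream reduction.** "Removing the redundant" 750 words per patient is
formalised as: drop duplicate letter strings keeping first occurrence,
truncate to the `L = 375` earliest or pad by cycling, yielding
constant-dimension classifier inputs in original segment order.

## The synthetic cohort

Real benchmark recordings are not redistributable, so the package ships a
generator whose defaults define the study conditions: 14 normal + 28 CVD
subjects, 100 Hz, 750 two-second segments each (150,000 samples). Each
beat is an asymmetric systolic Gaussian plus a delayed dicrotic bump;
records add baseline wander, a DC offset and white noise. The CVD class
beats faster and more irregularly (higher interval and amplitude jitter,
more skewed pulses, larger amplitude). A between-subject coefficient of
variation (default 0.07) individualises heart rate, amplitude, offset and
jitter per subject, which is what keeps the classification task
non-trivial: without it, every subject of a class is statistically
identical and all classifiers saturate at 100%.

What the generator does *not* emulate: motion artifacts, sensor
saturation, respiratory modulation, arrhythmic beat morphologies. Passing
tests therefore demonstrate that the pipeline's machinery is correct and
discriminates the modeled class differences — not that it reaches any
particular accuracy on clinical recordings.

**Feature calibration.** Raw features live on physical scales (energy is
a raw sum of squares, around 300–750 for the default cohort), while the
linguistic ranges are fixed small numbers. One affine map per feature
(`default_feature_scaling()`) bridges the two; the constants were
calibrated once against the default cohort by mapping the pooled 10th and
90th percentiles onto the Low-set and High-set peaks, then nudging the
skewness map so every feature keeps ≥ 95% of segments inside the union of
its linguistic ranges. They form the single tuning block of the
generator-to-fuzzifier interface and are not revisited per run.

## Diagnostics

**Rhythmicity** is the distinct-pattern fraction `R = C/D`; an ideal
singleton stream attains `1/D`.

**Hurst exponent** uses classic rescaled-range analysis: dyadic windows
from 8 to n/2, per-block range of the cumulative demeaned sum over the
block SD, and a least-squares slope on the log-log curve. The estimator
carries the well-known small-window upward bias for anti-persistent
series; the tests therefore check calibration in the mean over a few
simulations (white noise 0.5 ± 0.1 at n = 4096; fractional Gaussian noise
H ∈ {0.3, 0.7} recovered ± 0.1 at n = 8192, simulated exactly by circulant
embedding in the test helpers).

**Stream summaries** report moments, geometric/harmonic means (defined
because code-word values are strictly positive), lag-1 Pearson
autocorrelation — our reading of the "Pearson correlation coefficient"
column of this literature's summary tables, chosen because it measures
the serial uncorrelatedness those tables discuss, and configurable by
simply correlating any other pair — and sample/approximate entropy.
**Canonical correlation** between the normal and CVD optimized value
matrices is the first canonical correlation after truncating to common
dimensions, ridge-regularised (1e-6) for rank-deficient inputs.

## Optimizers

All four algorithms minimise over a box, are seeded, and are
bit-reproducible. Design choices where the source descriptions were loose:

- **Objective.** What "optimizing the fuzzy values" minimises is never
  stated. We use 1-D vector-quantization distortion — mean over stream
  values of the squared distance to the nearest representative — which
  operationalises the stated singleton-pattern goal and is zero exactly
  when representatives cover every observed value. The fitness is
  pluggable: every runner takes an arbitrary `fitness` function.
- **Seeding.** The reduced value vector joins the initial population, so
  greedy selection guarantees the optimized distortion never exceeds the
  raw reduction's.
- **DS.** Mask rates default to `0.3·U(0,1)` drawn once per run (the
  original convention); the gamma-distributed scale uses shape `2·U(0,1)`.
  Out-of-bound trial coordinates are re-drawn uniformly (the DS
  convention); the other three algorithms clamp.
- **SFLA.** The integer rounding in the published step rule is dropped —
  the search lives on a continuous value scale in `[0, 0.516]` where
  rounding would be destructive; the ±Rmax clamp is kept (default 20% of
  the bound range). Worst-frog updates try the memeplex best, then the
  global best, then random re-initialisation. Termination: shuffle budget
  or 50 stalled shuffles.
- **WS.** Grey-wolf style: elitist alpha/beta/delta leaders, control
  parameter declining linearly 2 → 0.
- **AMO.** Ring neighborhood of half-width 2 (five animals — the
  published example enumerates five indices even though the prose says
  ten; half-width is configurable), scalar Gaussian migration step,
  rank-based per-coordinate replacement probability (best 1/NP, worst 1),
  greedy selection after both phases.

## Classifiers and evaluation

The 375-value vectors are framed as five 75-value instances per patient —
our resolution of the stated 75-input network dimension against the
375-value vectors. Frames of one patient may land in different CV folds
by default, exactly as per-segment counting implies; `group_by_patient =
TRUE` provides leakage-free folds.

Classifier specifics: logistic regression (`glm`); a ridge-stabilised
Fisher discriminant; 5-NN with Euclidean distance and ties to the
positive class; an RBF network (30 k-means centers, width = mean
inter-center distance, linear least-squares output, 0.5 threshold); a
75-25-1 MLP with tanh hidden and logistic output units trained by
full-batch Rprop to MSE ≤ 1e-4 or 2000 epochs (the operationalisation of
"zero training error"); and an RBF-kernel SVM with γ selected from
{0.001, …, 0.01} by inner 3-fold CV on standardised inputs, with a
1800-row training subsample guard standing in for the stated
support-vector cap (never active at package scale).

The metric formulas are implemented exactly as printed in their source —
sensitivity `PC/(PC+FA)`, specificity `PC/(PC+MC)` — even though textbook
definitions differ; accuracy is identically their mean, the performance
index can go negative, and the good detection rate is `(PC−MC)/(PC+FA)`.
The MSE compares the classifiers' continuous outputs against per-class
target values, by default the class-wise modal target-code values.

## Problem sizes and numerical choices

The default full-scale run (42 subjects × 750 segments, wolf-search
optimization, six classifiers, 10-fold CV) completes in a few minutes on
one core; the test suite exercises it once at full scale and twice for
byte-identical reproducibility, and uses reduced record lengths
(25–150 segments) elsewhere, which preserves every structural property
while keeping the suite quick. Degenerate inputs are handled explicitly:
constant windows define ApEn/skewness/kurtosis as 0, constant series are
rejected by the Hurst estimator (R/S undefined), short streams return NA
entropies, and zero metric denominators yield NA rather than infinities.

## Known limitations

- The synthetic generator's class differences are stylised; reported
  accuracies on it say nothing quantitative about clinical data.
- The target-code construction and the 750 → 375 reduction rule are
  documented stand-ins for unspecified originals.
- The published headline accuracies require the original benchmark
  recordings and are deliberately out of scope; the pipeline reproduces
  the *structure* of those results (metric battery, optimizer ×
  classifier grid) instead.
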