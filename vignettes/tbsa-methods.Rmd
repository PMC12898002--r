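---
title: "Methods: tracheal breathing sound biomarkers for OSA severity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: tracheal breathing sound biomarkers for OSA severity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tbsa)
```

This vignette documents the models, estimators, and design decisions behind
`tbsa`, in the spirit of a statistical-methods appendix: what each stage
assumes, which knobs matter, and what the synthetic cohort can and cannot
tell you about real recordings.

## The measurement model

Wakeful tracheal breathing sound is modelled, for analysis purposes, as
band-limited (75–3000 Hz) airflow noise whose spectral placement, bandwidth,
impulsiveness, and nonlinear phase structure change with upper-airway
narrowing. The pipeline makes no physiological claim beyond this: every
downstream quantity is a descriptive statistic of the filtered mid-flow
signal, and the link to severity is established empirically through
cross-validated discrimination, stability, and correlation analyses.

Severity follows the standard AHI grading (Non < 5, Mild 5–15, Moderate
15–30, Severe ≥ 30 events/h). All six one-vs-one contrasts are evaluated
separately: features useful for `Non_vs_Severe` need not be useful for
`Mild_vs_Moderate`, and the per-pair gap regions make that explicit.

## The synthetic cohort: what it emulates, and what it does not

Real recordings of this kind are restricted-access, so the package generates
its own study material.

**Anthropometrics.** Per class, the continuous measures (AHI, age, BMI, neck
circumference) are drawn from truncated normal distributions. The truncation
supports are the class AHI bounds (for AHI) or plausibility bounds
(age ≥ 18, BMI ≥ 10, NC > 0), and the *underlying* normal parameters are
found by numerical optimisation so that the *truncated* distribution's mean
and SD equal the reference cohort values (74 Non, 35 Mild, 50 Moderate, 40
Severe subjects; e.g. severe AHI 69.5 ± 33.3). For the Non class the reference
AHI target (1.2 ± 1.3 on [0, 5)) is not attainable by any truncated normal —
the best fit achieves 1.30 ± 1.12 — so the sampler minimises the squared
moment error and reports the achieved moments in the result's `moments`
attribute rather than silently pretending otherwise. Sex and Mallampati
score are drawn from the reference category proportions.

**Acoustics.** Each breath phase is a raised-cosine envelope over coloured
noise: white noise band-pass filtered around a centre frequency (base 350 Hz
for nose inspiration; mouth breathing 15% higher, expiration 10% lower),
passed through a second-order autoregressive resonator whose pole radius is
the profile's `ar_regularity`, with Poisson impulsive bursts and a per-breath
amplitude gain of coefficient of variation `amplitude_cv`. The four severity
profiles form monotone ladders (centroid shift 0/60/130/220 Hz, bandwidth
scale 1.0/1.3/1.7/2.3, bursts 0.2/1/2.5/5 per breath, amplitude CV
0.05/0.12/0.22/0.35, regularity 0.90/0.85/0.75/0.60). These encode the
qualitative severity themes — escalating turbulence, bandwidth, centroid
shift, impulsiveness, variability — as *synthesis fixtures*, chosen once at
plausible magnitudes. They are not fitted to any physiology.

Recordings are five breath cycles (alternating inspiration/expiration,
durations ~1 s, 0.3 s silence gaps) per route at fs = 10,240 Hz — a rate
chosen, in the absence of a stated standard, to put the 3000 Hz analysis
edge comfortably below Nyquist — with a microphone noise floor at −40 dB
relative to breath RMS so SNR computation is exercised.

Consequently, a passing test suite demonstrates that the *pipeline* behaves
correctly (detects planted contrasts, respects leakage boundaries, reproduces
closed forms), not that real severity classes are separable at any particular
AUC. The synthetic Non-vs-Severe contrast is deliberately strong; real TBS
contrasts are far subtler, and real data add vocal artifacts, posture
effects, sensor variation, and between-subject acoustic heterogeneity that
the generator does not model.

## Preprocessing decisions

* **Filter**: Butterworth band-pass, design order 4 (8 poles), edges 75 and
  3000 Hz, applied forward–backward. Zero-phase filtering doubles the
  effective order and preserves envelope timing, which the segmenter relies
  on. Its 20 Hz attenuation exceeds 90 dB.
* **Segmentation**: log-variance envelope on 50 ms frames with 50% overlap;
  threshold = midpoint of the envelope's 5th and 95th percentiles (scale-free,
  hence gain-invariant); phases shorter than 200 ms are dropped and
  sub-threshold gaps shorter than 100 ms fused. Phases are labelled
  alternately starting from inspiration, matching the recording protocol;
  recordings that begin mid-cycle can set `start_phase`. An all-silent input
  (envelope dynamic range below ~1 nat) returns an empty segment list.
* **SNR gate**: 5 dB default; gated segments are flagged (`retained = FALSE`)
  rather than deleted, so a user can audit what was excluded.
* **Mid-flow**: the central 50% of each phase, centred on the smoothed
  envelope peak — the high-flow portion where airway noise dominates.

## Gap regions

For a class pair, per route×phase condition, the per-subject mean PSD
(Welch, 1024-point Hann, 50% overlap; ~10 Hz resolution) and mean bispectrum
(direct method, 256-point segments, principal domain
`0 ≤ f2 ≤ f1, f1+f2 ≤ fs/2`) are bootstrapped over *subjects* (the
exchangeable unit in a cohort; resampling breaths would understate
between-subject variance) to percentile 95% CIs. Bins where the class CIs do
not overlap are gap bins; 1D runs of at least 2 bins become gap bands, and
8-connected 2D components of at least 4 cells become gap boxes (tight
bounding boxes, largest first). Wider CIs can only remove gap bins, so the
detection is monotone in the confidence level.

Gap learning runs strictly on each fold's training subjects and the learned
regions are frozen before test-subject features are extracted — the
package's equivalent of a pre-registered region of interest. When a
training split is too small (< 3 subjects per class) or produces no gap, the
"Range" context falls back to the full analysis band and the "BBox" context
to the whole principal domain; this keeps the feature-name space stable
across folds at the cost of diluting the context distinction, and is the
main reason tiny smoke cohorts show many `Full`-like duplicates.

Feature names are `<Condition>_<Context>_<Descriptor>` with condition one of
the four route×phase pairs or `Average` (the mean over available
conditions), and context `Full`, `Range`, or `BBox<i>` (boxes indexed by
descending component size, coordinates kept in the report metadata). The
grammar is parseable and round-trips (`parse_feature_name()`).

## Estimator choices and numerical details

* **Welch PSD** uses density scaling (integral ≈ variance), verified by a
  Parseval test.
* **Jitter/shimmer/NHR** require detected periodicity (autocorrelation peak
  ≥ 0.3 in 60–400 Hz); zero-crossing times are linearly interpolated to
  sub-sample precision so a pure sampled tone reports jitter ≈ 0. Without
  periodicity the three metrics are `NA`, never fabricated; the pipeline
  later drops columns that are missing in > 20% of subjects and imputes the
  rest with the column median.
* **Hurst exponent** uses R/S analysis with the Anis–Lloyd small-sample
  correction; without it, white noise at desk-scale lengths reads ~0.6
  rather than 0.5.
* **Lyapunov (Rosenstein)** reports the slope of the initial linear region
  of the mean log-divergence curve, in 1/sample units; the fit range is
  configurable because the linear region depends on the system.
* **RQA** uses a radius of 0.1× the phase-space diameter, embedding m = 3,
  delay = first autocorrelation zero, Theiler window = delay. Diagonal
  structures are counted on both triangles of the symmetric recurrence
  matrix.
* **O(n²) estimators** (RQA, Lyapunov) operate on the mid-flow signal
  decimated to ≤ 400 samples inside the pipeline (standalone calls accept
  any length). This bounds the per-subject cost while leaving the
  known-limit behaviour intact.
* **Wavelets**: periodized orthogonal db4 transform, 5 levels, so level
  energies partition signal energy exactly (tested to 1e-8 relative).
* **GLCM**: 8 grey levels, distance-1 horizontal/vertical offsets,
  symmetric and normalized; quantization is range-relative, making texture
  descriptors invariant to global gain.
* **Morphology**: 8-connectivity for foreground, 4 for background holes
  (the standard duality avoiding connectivity paradoxes); perimeter is the
  exposed-edge count (integer, exactly testable); the bounding-box diagonal
  is measured between opposite corner-cell centres; Otsu binarization on a
  256-bin histogram, with a degenerate (constant) region yielding an
  all-false, flagged mask.
* **Tree-SHAP** is the exact path-dependent algorithm on parsed CART trees;
  it was validated against a subset-enumeration Shapley oracle and satisfies
  additivity to numerical precision, which the tests assert at 1e-6.

## Normalization and selection

Four candidate normalizations (mean-range, z-score, min-max, robust) are
compared by the mean mutual information between normalized features and the
class label, estimated with equal-frequency binning at ⌈√n⌉ bins — a
deterministic estimator with no tuning. Statistics are learned on training
rows only. Because MI under fixed binning is invariant to strictly monotone
maps, the four methods tie on clean data and the fixed preference order
(mean-range, z-score, min-max, robust) resolves the choice; the machinery
exists for data with outliers or zero-variance columns (passed through and
flagged).

Selection is per pair, inside each training fold: (1) univariate filter
keeps the 200 features with highest |AUC − 0.5| (rank-sum AUC, ties broken
lexically); (2) a bagged CART ensemble is ranked by mean |SHAP|; (3) RFE
drops the lowest-importance 10% per iteration to a fixed 35-feature subset
(both configurable; smoke tests use smaller values). SHAP importance ties —
common when correlated features split identically, leaving all but one with
zero attribution — are broken by the univariate AUC score rather than column
order, so redundant-but-informative features survive ahead of noise. The
recovery property (planted informative features retained) is tested across
seeds.

## Cross-validation and metrics

The stratifier snake-deals subjects within each severity class in composite
z-score order, then accepts pairwise swaps that lower a balance cost:
squared standardized fold-mean deviations for continuous criteria plus a
χ²-style divergence for sex and Mallampati categories, all criteria equally
weighted after standardization. Fold sizes stay within ±15% of n/k. k = 3
by default. Classes smaller than k trigger a warning and may be absent from
some folds.

Ensembles are 100 bagged CART trees (unpruned; bootstrap resamples of
training subjects; score = mean positive-class probability). AUC is the
Mann–Whitney rank statistic with ties credited 0.5, verified against
exhaustive pair counting. Per-feature stability uses the fold-averaged
absolute train−test deltas of the single-feature AUC and of the Pearson
correlation between the feature and the binary pair label:
stable ⇔ ΔAUC ≤ 0.01 and Δcorr ≤ 0.1; slightly unstable ⇔ ΔAUC ≤ 0.01 and
Δcorr ≤ 0.15; otherwise unstable. Correlation-based and SHAP-based ranks
(minimum rank on ties, averaged across folds) are combined by arithmetic
mean into the overall rank. Fold-wise Pearson correlations between features
and anthropometric variables (sex coded 0/1, Mallampati as integers) are
reported for interpretation only and never feed back into training.

## Problem sizes used in the shipped checks

The test suite and acceptance script run at desk scale by choice: cohorts of
8–40 subjects, k = 2 folds, 50–100 bootstrap replicates, 10–40 bags, and
selection to 8–20 features; the anthropometric checks use 4,000–20,000
draws. The defaults in `tbs_config()` (k = 3, 200 bootstrap replicates, 100
bags, 200→35 selection) are sized for realistic cohorts of one to a few
hundred subjects.

## Known limitations

* The acoustic profiles are fixtures; absolute AUCs on synthetic cohorts say
  nothing quantitative about clinical performance.
* Gap-region fallbacks blur the Range/Full distinction on very small
  training splits.
* Phase labelling trusts the protocol's inspiration-first convention; there
  is no airflow channel to verify it.
* Jitter/shimmer/NHR are usually undefined on broadband breath noise and are
  carried mainly for completeness of the time-domain family.
* The bagged-tree score is not calibrated as a probability, and the six
  pairwise models are not fused into a single four-class decision rule.
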