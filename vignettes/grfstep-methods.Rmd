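---
title: "Methods: step parsing, feature selection and subject-specific classification of insole GRF data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: step parsing, feature selection and subject-specific classification of insole GRF data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`grfstep` turns continuous three-region insole ground-reaction-force (GRF)
recordings — heel, midfoot and forefoot vertical force at 100 Hz — into
step-level classifications of the loading condition a subject was walking
under (treadmill speed x incline). This vignette documents the model and
procedure choices, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical
conventions.

## The pipeline

Each subject is processed independently, in four stages:

1. **Step parsing.** Continuous recordings are segmented into gait cycles
   by combining peak detection and signal-intersection analysis.
2. **Feature extraction.** Each step's three channels are zero-padded to a
   common length, min-max scaled to `[0, 1]` on training data, and expanded
   into a large bank of statistical, temporal and frequency-domain summary
   features.
3. **Feature selection.** Correlated features are pruned by single-feature
   model performance; the survivors are ranked by one-way ANOVA F-score and
   truncated at a K chosen by the one-standard-error rule over stratified
   5-fold cross-validation.
4. **Classification.** A Random Forest predicts the condition code of each
   held-out step; performance is summarized as Top-1/2/3 accuracy and
   weighted precision/recall, and the same features/partition are re-used
   to retrain speed-only (3-class) and incline-only (6-class) models.

## Step parsing

A heel strike is operationalized as the heel signal's last upward crossing
of the 1 N event threshold before a detected heel peak; a toe-off as the
forefoot signal's first downward 1 N crossing after the following forefoot
peak. A step (gait cycle, in this package's sense) is the half-open sample
interval `[heel_strike, toe_off)` — the stance phase.

Peaks are local maxima above 7 N (forefoot) or 3.5 N (heel), with
candidates closer than 80 ms pruned greedily from the highest down (ties
toward the earlier sample). A flat two-sample plateau strictly above its
flanks counts as one peak at its first sample: sampled smooth waveforms
(and quantized sensors) routinely produce exact ties at a peak, and a
strict-inequality rule would silently drop those peaks.

Intersection analysis finds samples where the sign of the pointwise
difference of two signals reverses: heel vs. total (initial contact),
forefoot vs. heel (midstance), forefoot vs. total (toe-off). Exact-zero
differences inherit the previous nonzero sign, so a difference touching
zero without crossing is not an event, and the reported index is the first
sample on the new side. Crossings are refined to those where one signal is
within 0.5 N of zero, which is what distinguishes stance-swing transitions
from mid-stance wiggle. These intersections annotate the segments; step
boundaries come from the peak-anchored threshold logic above, so a missing
midstance annotation never invalidates a step. For the midstance
annotation specifically we keep the crossing at which the forefoot
overtakes the heel (positive difference side): the opposite-direction
crossing occurs trivially near initial contact, where the forefoot is
still silent.

Two unit conventions deserve note:

- **Thresholds are raw Newtons.** Peak (7 / 3.5 N) and event (1 N)
  detection run on unnormalized signals, so the printed thresholds apply
  verbatim; a body-weight-normalized recording is converted back
  internally.
- **The noise floor is 1.5 N, normalized.** The intersection-analysis
  copies are body-weight normalized and floored at `1.5 N / body weight`.
  Reading the floor as 1.5 *body weights* instead would zero every
  physiological sample (walking GRF peaks near 1.2 BW), making
  intersection analysis vacuous, so the package fixes the
  Newtons-divided-by-body-weight reading.

The total-foot signal is defined as the sum of the three regional
channels — the only combination consistent with an insole's regional
decomposition.

Candidate bookkeeping (emitted / rejected-for-missing-onset / truncated /
overlap-discarded, with the identity `candidates = sum of the four`) is
exposed by `validate_steps()` as an automated stand-in for visual
inspection; overlapping candidates discard the later step.

All indices in the R API are 1-based, following the language's convention;
file outputs carry event *times* in seconds, so the on-disk interface is
index-free.

## Synthetic gait generator

Real insole data of this kind is not freely redistributable, so the
package ships a generator that emulates the statistical structure the
pipeline relies on, with exported ground truth:

- each stance phase is built from half-sine bumps: heel peaking at ~25% of
  stance, forefoot at ~75%, a low midfoot bump in between; swing is silent;
- walking speed drives cadence (step period 1.1 s at 1.2 m/s, scaling as
  `speed^-0.5`) and adds amplitude (0.15 BW per m/s above 0.8 m/s);
- incline transfers load from heel to forefoot at 0.012 BW/degree (heel
  floored at 0.1 BW), so uphill conditions are forefoot-dominant;
- step-to-step variability: period jitter (CV 0.03) and peak-amplitude
  jitter (CV 0.05). The amplitude jitter matters: adjacent incline classes
  differ by only 0.06 BW in peak force, and ~5% step-to-step peak
  variability — a standard observation in repeated gait trials — makes
  neighboring inclines overlap while speeds stay well separated, which is
  exactly the confusion structure the classification stage should face;
- sensor noise is additive zero-mean Gaussian with SD 2 N at the
  transducer's oversampled rate, decimated by averaging 10 draws per
  emitted 100 Hz sample (in-band RMS ~0.63 N), then clipped at 0 N since
  forces are non-negative. Modeling the acquisition chain's decimation
  matters: white 2 N noise left unfiltered at 100 Hz would exceed the
  3.5 N heel-peak threshold about once per swing phase (a simple
  exceedance-rate argument), flooding the parser with spurious peaks that
  no insole actually produces — real transducer chains are band-limited;
- the truth table records, per step, the first sample at which the heel
  exceeds the 1 N event threshold and the first sample at which the
  forefoot has returned to zero, so with noise and jitter disabled the
  parser must recover every event at the exact sample, and does.

Subject-level heterogeneity: body weight uniform on 500-1000 N and
amplitude parameters within +/-15% of defaults, drawn per subject from
seeds derived deterministically from the master seed (adding a subject
never changes the others).

What the generator does **not** emulate: double-support force sharing,
kinematic coupling, sensor drift, fatigue trends within a session, or any
within-class temporal correlation beyond the waveform itself. Passing
tests on synthetic cohorts therefore demonstrate that the pipeline's
machinery is correct and that its comparative patterns (speed easier than
incline; Top-2/3 much higher than Top-1) emerge under controlled effect
sizes — not that real-data accuracy equals the synthetic numbers.

## Feature bank

No comprehensive time-series feature extractor of the tsfresh variety
exists for R in this package's dependency set, so the bank is implemented
here: ~800 named candidates per channel across moments, quantiles,
run/crossing statistics, autocorrelation and partial autocorrelation (lags
1-10), nonlinearity statistics (c3, time-reversal asymmetry, cid_ce),
change-quantile corridors, chunked aggregates and energy ratios, a
linear-trend block, spectral moments, and an FFT coefficient grid (150
bins x abs/real/imaginary/angle). Three channels give ~2400 candidates
(~3200 with the optional total-foot channel). Names are data-independent:
features undefined at a given series length (FFT bins beyond Nyquist,
long-lag statistics on short series) are emitted as `NA` and removed by
`drop_invalid_features()`, which also drops zero-variance columns (an
F-score is undefined on a constant). Validity is judged on training rows
so held-out steps cannot influence the surviving column set.

Padding precedes extraction (so length itself becomes signal — padded
zeros encode step duration identically across channels), and the min-max
scaler is fitted on training steps only; held-out values may fall outside
`[0, 1]` and are deliberately not clipped.

## Feature selection

Stage one groups features greedily in column order at `|r| > 0.8` and
keeps, per group, the member with the best 3-fold stratified CV accuracy
of a depth-5 single-feature decision tree (`rpart`); ties go to the
lexicographically first name so reruns are identical. A depth-limited tree
is the smallest model family that can split 18 classes on one feature;
3-fold (rather than 5) keeps the per-feature cost proportionate since this
stage only needs a ranking within small groups.

Stage two ranks survivors by one-way ANOVA F and evaluates K in
{5, 10, 15, 20, 30, 40, 50, 75, 100} (a decade-spanning default grid; the
choice of grid is not critical because the 1-SE rule is applied to
whatever grid is supplied) with stratified 5-fold CV of the downstream
forest. The standard error is the fold-accuracy SD divided by sqrt(5) at
the best K only — the classical one-standard-error rule — and the chosen K
is the smallest one within that band. Stratification throughout is
non-optional at this scale: with ~12 steps per class in a small subject,
plain random folds can lose classes entirely.

Selection sees training rows only; the test suite verifies that permuting
held-out rows changes nothing in the selection result. Note that the
internal CV curve is optimistically biased under the null (the F-ranking
sees the same rows the curve is computed on); honest generalization is
measured on the held-out 20%.

## Classification and evaluation

The 80/20 split is stratified per class rather than fully random: with 18
classes and a few hundred steps, an unstratified split can orphan a class
from training entirely, which stratification rules out. The Random Forest
uses 100 trees and unlimited depth — defaults, with no hyperparameter
search — and all seeds are surfaced in the configuration.

Ranked predictions sort class probabilities with ties broken by ascending
class code, making Top-k deterministic. Weighted recall is algebraically
identical to Top-1 accuracy (the per-class supports are the weights), a
property the tests assert on random inputs. Axis re-projection (speed-only
/ incline-only) retrains on the same features and partition with projected
labels — features are deliberately not reselected, isolating the effect of
the label space.

Cohort aggregation reports mean, median (midpoint of the middle pair for
even cohorts) and *population* standard deviation (divide by n): on the
shipped reference table of published per-subject metrics, the population
formula reproduces the printed dispersion (0.053) where the sample formula
gives 0.055. Mean sample size is displayed with half-up integer rounding
(467.57 -> 468). Metrics print at three decimals and chance accuracy at
four (1/18 = 0.0556).

## Problem sizes and determinism

Default end-to-end runs (tests and the acceptance script) use 14 simulated
subjects x 18 conditions x 20 s per condition (~320 steps/subject), with
module-level tests on smaller grids; these sizes exercise every stage at
the study's class structure while keeping a full cohort run in minutes on
one core. Every stochastic stage (simulation, splits, fold assignment,
tree/forest fitting) flows from one master seed via fixed arithmetic
derivations, and reruns are bit-identical at the prediction level.

## Known limitations

- Steps from one recording are temporally correlated; holding out 20% of
  steps within the same session estimates within-session accuracy, not
  cross-session generalization. This matches the subject-specific
  monitoring use case but should not be read as an independent-sessions
  claim.
- The parser targets walking stance phases on treadmill-like recordings;
  running, stair gait and bilateral synchronization are out of scope.
- The generator's waveforms are analytically convenient half-sines, not
  measured templates; absolute synthetic accuracies are not comparable to
  real-data accuracies (the comparative structure is).
- The correlated-pruning stage is greedy and order-dependent by design
  (first-fit grouping in column order), trading optimality for
  reproducibility and speed.
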