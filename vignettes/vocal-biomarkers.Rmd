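---
title: "Vocal biomarkers for neurological screening: models, parameters and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Vocal biomarkers for neurological screening: models, parameters and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vocalmarkers)
```

## The problem

Dysarthria — the motor speech disorder that accompanies Parkinson's disease,
multiple sclerosis and other neurological conditions — leaves measurable
traces in phonation long before speech becomes overtly impaired: the glottal
cycle becomes irregular in period (jitter) and amplitude (shimmer), turbulent
noise rises against the harmonic structure (lower harmonic-to-noise ratio),
the vowel space contracts as articulation centralizes, and the cepstral
organization of the signal degrades. `vocalmarkers` implements a complete
screening pipeline over sustained-vowel and short speech recordings: 28
biomarkers across three domains, a dataset pipeline, five classifier families
with the standard confusion-matrix metrics, and Shapley-value explanations of
individual predictions.

Because clinical recordings cannot be redistributed, the package is built
around a synthetic voice generator with exact ground truth; every stage of
the pipeline is validated against quantities the generator knows by
construction.

## The synthetic voice model

A voiced sound is modeled as a quasi-periodic train of glottal pulses passed
through vocal-tract resonances:

* each cycle `i` has period `T0 * (1 + eps_i)` and peak amplitude
  `1 + delta_i`, with `eps`, `delta` i.i.d. zero-mean Gaussians truncated at
  ±3 sd. The sds are calibrated so that the *realized* relative perturbation
  (mean absolute consecutive difference over the mean — the same statistic
  the jitter/shimmer extractors report) equals the requested `jitter_rel` /
  `shimmer_rel`: for `eps ~ N(0, s)`, `E|eps_i - eps_{i-1}| = 2 s / sqrt(pi)`,
  so `s = target * sqrt(pi) / 2`.
* the pulse is a smooth unipolar raised-cosine burst of 0.25 ms. The width
  matters twice over: a burst much wider than this (say half a period) has no
  source energy left near 3.5 kHz, so the fourth formant of a filtered vowel
  is unrecoverable by any spectral-envelope method; a single-sample impulse,
  at the other extreme, makes cepstral analysis degenerate. 0.25 ms keeps the
  source band-limited and smooth while exciting resonances up to F4.
* vowels are produced by cascaded two-pole resonators at the preset formant
  frequencies (Peterson–Barney-range adult values for /a e i o u/,
  bandwidths 80–160 Hz), each normalized to unit gain at resonance.
* noise is band-limited Gaussian, scaled *after* any vocal-tract filtering so
  that the stored clean/noise components meet the `hnr_db` target exactly.
  Generators return a ground-truth sidecar (pulse times, pulse amplitudes,
  clean and noise components), so tests of the extractors never depend on
  the pitch tracker they are testing.

The generator is an engineering stand-in for pathological phonation, not a
disease model: elevated jitter/shimmer and reduced HNR mimic the direction
of dysarthric change, but nothing here captures disease-specific
articulatory dynamics, voice breaks, diplophonia, or tremor. Passing tests
demonstrate that the measurement chain is correct, not that the classifiers
would reach any particular accuracy on clinical recordings.

## Cycle estimation

All perturbation measures derive from the cycle series (periods `T_i`,
peak-to-peak amplitudes `A_i`). The tracker proceeds in two stages:

1. **Coarse F0 and voicing.** Normalized autocorrelation of 40 ms frames
   (20 ms hop), searched over lags for 60–500 Hz (configurable). Frames with
   a peak below 0.45 are unvoiced; marginal frames (≥ 0.6 × threshold)
   adjacent to voiced ones are kept by hysteresis, which prevents a
   perturbed-but-periodic stretch from fragmenting into many short runs.
   The autocorrelation runs on low-passed copies of the signal: a wide band
   (2.5 × f0_max) for the voicing decision — broadband noise decorrelates
   there and is rejected — and a narrow band (1.5 × f0_max) for the period
   estimate. The narrow band spreads each glottal pulse across most of its
   cycle, so cycles still overlap at lag `T` under several percent of
   jitter; without it, narrow pulses decorrelate and short runs lock onto
   octave-doubled periods.
2. **Cycle landmarks.** Within each voiced run, waveform peaks are picked
   marching forward and backward from the strongest extremum, searching
   ±30% of the local period, with parabolic interpolation for sub-sample
   positions. Amplitudes are per-cycle peak-to-peak values with both extrema
   parabolically refined — without the refinement, sample quantization alone
   injects spurious shimmer on the order of 1%, swamping the smallest
   clinically meaningful levels.

Speech items are analyzed per contiguous voiced run and the cycle series
concatenated; periods never bridge unvoiced gaps.

## The 28 biomarkers

**Acoustic (17).** F0; F1–F4 by linear prediction on the signal decimated
toward ~11 kHz (pre-emphasis 0.97; autocorrelation averaged over 30 ms
Hamming frames, which suppresses the harmonic fine structure a single long
window imprints on the envelope; model order 12 per 5.5 kHz of bandwidth;
resonance candidates are pole angles with bandwidth < 400 Hz). Five jitter
and six shimmer metrics are implemented exactly as the source formulas are
printed, including their unusual normalizations (the absolute-jitter sum of
`N-1` consecutive differences carries a `1/N` prefactor; the relative-metric
denominators average the first `N-1` periods with a `1/N` factor; the
difference-of-differences metrics reduce to rescaled versions of the plain
mean absolute difference). Two readings required interpretation: the
`APQ_n` neighborhood term is read as the mean of the `n-1` amplitudes at
offsets `k ∈ [-n/2, n/2] \ {0}` — the literal `1/n` prefactor over `n-1`
terms would make `APQ` of a perfectly steady voice nonzero, contradicting
its role as a perturbation measure — and the dB-shimmer sum is kept exactly
as printed (no absolute value, so it telescopes); `classical = TRUE`
switches both families to the textbook MDVP-style definitions. HNR is
reported in the standard orientation, `10 log10(harmonic/noise)` clipped to
[-20, 40] dB (the printed ratio is inverted relative to its own name; the
discrepancy is documented rather than silently adopted), estimated by
cycle-synchronous comb averaging: the mean resampled cycle is the harmonic
template, per-cycle residuals estimate the noise, with corrections for the
template's own noise floor (`P_n/M` over `M` cycles) and for the white-noise
attenuation `(1-f)^2 + f^2` of linear interpolation at fractional positions.

**Articulation (3).** tVSA (triangle /i a u/), qVSA (quadrilateral
/i e a u/) in the (F1, F2) plane, and FCR
`(F2u + F2a + F1i + F1u) / (F2i + F1a)`. The printed area formulas are
signed; absolute values are reported since an area is non-negative and
vertex orientation is otherwise unspecified. These are cross-vowel,
per-subject quantities: formants are averaged over a subject's phonations
of each vowel, and the three features are broadcast onto every record of
that subject — speech-only subjects get missing values, handled by the
imputation step.

**Cepstral (8).** Mean and median of: the flattened MFCC matrix (13
coefficients, 26 mel filters, 2048-sample frames, 512 hop); CPP (60 Hz
high-pass, Hann window, real cepstrum of the dB spectrum, peak within the
quefrency band for 60–500 Hz, normalized by subtracting a regression-line
trend fit over that band — the classic cepstral-peak-prominence practice);
ZCR (sign changes per sample, with exact zeros contributing half a change
on each side so crossings through zero samples still count); and spectral
centroid (magnitude-weighted mean frequency, silent frames excluded).

## Dataset pipeline

Consolidation walks `<root>/<subject>/<content>_<k>.wav`, extracts each
record's features (individual extractor failures become missing values,
never aborted records) and writes a structured CSV. Preprocessing imputes
missing cells with the column mean and z-scores with population-sd
parameters — both estimated on the *fitting rows only* (by default the
training part) and applied everywhere. Fitting on the training part is the
package default because fitting on the full table lets test-set statistics
leak into the scaler; a `fit_rows = seq_len(nrow(tbl))` call reproduces the
full-table behavior when fidelity to that convention is wanted. Class
balancing duplicates minority-class *waveforms* with a speed perturbation
drawn from [0.99, 1.01]; augmented records are flagged and barred from test
splits, again to keep near-duplicates from inflating test metrics. The
stratified record-level split uses round-half-up of `fraction × N` (which
reproduces 317/739 from 1056 at 30% and 134/536 from 670 at 20%) with
largest-remainder per-class quotas. Splitting is by record, not by subject;
records of one subject can appear on both sides, a known caveat of
record-level evaluation that is kept for fidelity to the evaluated design.

## Classifiers, metrics, explanations

The five families use the published hyperparameters as defaults: SVM (RBF,
gamma 0.1, C = 1 — "moderate penalty" is not otherwise quantified), gradient
boosting (depth 6, learning rate 0.1, 100 rounds), decision tree (depth 8,
at most 23 leaves — enforced by walking the complexity path — minimum split
2, entropy), random forest (4 features per split, 40 trees), kNN (k = 10,
Manhattan distance, inverse-distance weights; implemented by brute force, so
the stated leaf size has no effect on results). Binary metrics take class 1
(pathological) as positive; multiclass metrics are unweighted one-vs-rest
macro averages, since the evaluated design reports single scalars without
naming a rule. MCC with a vanishing margin factor is defined as 0. ROC
curves come from a threshold sweep over out-of-fold scores of a stratified
3-fold cross-validation, AUC by the trapezoidal rule; constant scores give
the chance diagonal.

Shapley attributions use the weighted-average-over-subsets definition with
weights `|S|! (|F|-|S|-1)! / |F|!`. Two value functions realize the
coalition game: retraining on each feature subset (the literal definition;
exponential cost, capped at 12 features) and marginal-expectation masking
over a seeded background sample of at most 100 training rows (the practical
default for 28 features). In both, `v(∅)` is the mean training prediction,
so the efficiency axiom reads `sum(phi) = f(x) - baseline`. Explanations are
computed on the margin (log-odds) scale rather than the probability scale,
matching the convention of force-style local reports; an instance is
oriented "healthy" when its output falls below the baseline and
"pathological" otherwise, with ties counted pathological.

## Numerical choices and degenerate inputs

* Pitch range defaults 60–500 Hz; voicing threshold 0.45; all exposed.
* Fewer than 5 detected cycles, or a mean cycle rate outside the pitch
  range, is an insufficient-voicing error; per-metric cycle-count
  preconditions (PPQ5 ≥ 5, APQ11 ≥ 12, …) raise errors in direct calls and
  yield missing values in pipeline mode.
* Zero-variance columns standardize to zero with a warning; all-missing
  fitting columns are an error naming the column.
* Noiseless HNR hits the +40 dB clip; pure noise is rejected as unvoiced.
* Degenerate (collinear) vowel inventories give zero areas and FCR = 2.
* WAV I/O is 16-bit PCM; round-trips are exact to one quantization step.

## Problem sizes used in the test suite

The suite validates on compact material chosen to exercise every code path:
mostly 0.3–1 s phonations (16 kHz for pipeline plumbing, 44.1 kHz — the
acquisition-protocol rate — for recovery studies), 20-seed averages for
stochastic recoveries, 100-case oracle sweeps for the closed-form metrics,
and a 12-subject synthetic cohort for the end-to-end run. The classifier
sanity checks use the 100 + 100 record table with class means 3 sd apart on
5 features.

## Known limitations

* The generator's pathology model is perturbation-only; no tremor,
  voice breaks, or disease-specific articulatory dynamics.
* A single greedy decision tree at the stated hyperparameters plateaus
  around 95% holdout accuracy on the separable synthetic table; seeds exist
  on either side of that line. The ensemble methods do not share this
  ceiling.
* Formant estimates of high vowels bias F1 upward by ~10–20% (a known
  weakness of low-order LPC near strong F0 harmonics); F1/F2-based
  vowel-space features remain well ordered.
* Record-level splitting can share subjects across train and test.
* MFCC statistics summarize the flattened coefficient matrix, not
  per-coefficient aggregates.
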