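---
title: "Methods: multimodal fatigue detection from eye tracking and ECG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal fatigue detection from eye tracking and ECG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models and the design
choices behind them: what each stage assumes, which constants matter and
why they hold their defaults, what the synthetic cohort generator does and
does not emulate, and where the numerically delicate corners are.

## 1. Problem setting

An operator monitors a panoramic screen array for long stretches; we
observe two wearable signals — gaze (angles in degrees of visual angle plus
pupil diameter at a nominal 100 Hz) and a single-lead ECG (512 Hz) — and a
subjective 7-point fatigue rating (Samn–Perelli, SP-7) collected after each
work scenario. The task is to decide, for every non-overlapping 60-s
window, whether the operator was alert (SP-7 1–3) or fatigued (SP-7 5–7);
the ambiguous middle rating (4) is excluded from supervised fitting but
retained in all tables. Fatigue windows are rare (≈ 17:1 imbalance) and
missing them is the costly error, which drives every modelling choice
below.

## 2. Ocular chain

**Blink repair.** Wearable trackers emit zero pupil diameter when the eye
is closed or the pupil is lost. Zero-runs are partitioned by duration:
< 75 ms is treated as a tracker dropout (x, y, pupil linearly
interpolated; not an oculomotor event); 75–500 ms is a normal blink (gaze
coordinates interpolated to preserve the scanpath, pupil left at zero so
closure accounting still sees it); > 500 ms is a long eyelid closure whose
samples are excluded from fixation parsing altogether. A stream whose
pupil is zero throughout is flagged unusable instead of being fabricated
by interpolation.

**I-VT.** Fixations and saccades are separated by angular velocity with
the conventional 30°/s threshold; the boundary sample (exactly 30°/s)
counts as saccade. Velocity uses central differences (forward/backward at
the stream edges). Runs are split at blink/closure samples — so a blink
interrupts a fixation and yields two fixation events; this is one of two
defensible readings and is applied consistently (it slightly deflates MFD
and inflates FF on blink-heavy windows). Fixations shorter than 100 ms (a
common I-VT convention; configurable) are re-labelled saccade.

**Features.** PERCLOS is implemented as the fraction of window time with
zero pupil — a proxy for the classical "eyelid covers ≥ 80% of the pupil"
criterion, stated openly as such because wearable-tracker data carry no
eyelid aperture. BF and FF are per-minute rates so 60-s windows give
counts directly; MBD and MFD are mean event durations (a window with no
blinks reports MBD = 0; no fixations reports MFD = 0 plus a quality flag);
PDV is the within-window standard deviation of pupil diameter over valid
open-eye samples ("variability" is not defined more precisely anywhere we
could anchor to, and the SD is the least exotic reading).

**Gaze entropies.** The display is tiled by an M × N grid of areas of
interest; the default 4 × 8 spans a three-screen panorama (the grid
dimensions are not prescribed by the source material; both are
configurable). Stationary gaze entropy is the Shannon entropy (bits) of
the fixation-share distribution over non-empty cells, unnormalized —
H ≤ log2 K for K non-empty cells. Transition gaze entropy is the
conditional entropy of the first-order AOI transition chain with
empirical source-cell weights; self-transitions count (nothing in the
defining formula excludes i = j). Fewer than one (SGE) or two (TGE)
fixations yield 0 with a quality flag rather than an error.

## 3. Cardiac chain

**Denoising.** 8-level discrete wavelet transform with the sym8 basis.
Since no wavelet package exists in our dependency set, the transform is
implemented in-package as the standard orthonormal pyramid with periodic
boundary handling (analysis operator orthogonal ⇒ synthesis is its
transpose ⇒ perfect reconstruction, which the tests assert to 1e-10).
Detail coefficients are soft-thresholded with the universal threshold
λ = σ√(2 log N); σ is estimated from the finest detail level by
MAD/0.6745 (the λ definition does not fix σ's estimator; this is the
standard robust choice). The level-8 approximation (0–1 Hz at 512 Hz) is
zeroed, which removes baseline wander. Non-dyadic lengths are padded by
symmetric reflection and unpadded on return.

**R-peaks.** Pan–Tompkins in its classic form: zero-phase 5–15 Hz
Butterworth band-pass, five-point derivative, squaring, moving-window
integration with W = 150 ms, adaptive dual-threshold peak picking with a
200 ms refractory period and half-threshold search-back. Only the W
constant and the algorithm name are externally fixed; the internals follow
the published detector. Detected envelope peaks are refined to the local
maximum of the band-passed trace within ±40 ms. Candidate envelope maxima
must dominate a half-refractory neighbourhood — without this, numerical
ripple on envelope flanks produces spurious early candidates that the
refractory logic then locks onto. A trace is flagged implausible when the
detected rate leaves 40–180 bpm **or** the RR coefficient of variation
exceeds 0.20: pure-noise inputs can produce in-range rates by chance, but
their RR trains are several times more irregular than any resting rhythm.

**RR cleaning and HRV.** RR intervals deviating strictly more than ±20%
from the mean of their up-to-5 nearest accepted neighbours (excluding
self) are removed in a single left-to-right pass; each removal leaves a
gap flag. The neighbour count and single-pass policy are our choices (the
rule's window is not prescribed). SDNN uses the N−1 denominator; RMSSD
uses only gap-free consecutive pairs — interpolating across a removed
ectopic would fabricate exactly the variability the removal was meant to
protect. For LF/HF, the unevenly sampled tachogram is cubic-spline
interpolated to a uniform 4 Hz grid (field convention), linearly
detrended, Hann-tapered, and band powers are trapezoid-integrated over
0.04–0.15 and 0.15–0.40 Hz. A 60-s window resolves 0.0167 Hz, so the
bottom of the LF band is poorly resolved; this is a faithful limitation of
windowed spectral HRV, not a defect to be papered over. HF = 0 yields
LF/HF = 1e6 with a flag instead of a division error.

## 4. Dataset assembly

Windows are aligned to scenario start, half-open, non-overlapping, 60 s;
trailing partial windows are dropped. A window is rejected (with a logged
reason) when more than 30% of its gaze samples are invalid, its cardiac
chain is flagged unusable, or its heart rate is implausible — the source
material's artifact-rejection rule is unquantified, so these three
concrete rules stand in for it. The 12-vector is the serial concatenation
(PERCLOS, BF, MBD, MFD, FF, PDV, SGE, TGE, MeanRR, SDNN, RMSSD, LFHF); no
scaling happens at fusion time because normalization statistics are a
training-set-only object. Label validation runs Spearman's rank
correlation between SP-7 and PERCLOS and a pooled-variance two-sample
t-test of PERCLOS between label groups (a Welch switch exists; pooled is
the default because the variant was not specified).

## 5. Classifier

Z-score normalization is fitted on training rows only; zero-variance
features map to 0. SMOTE generates synthetic fatigue samples along
segments between a minority point and one of its k = 5 minority
neighbours, drawn in normalized space (distances are scale-sensitive;
running SMOTE on raw features would let MeanRR dominate the metric). The
synthetic count targets a 0.5 minority/majority ratio by default — enough
to matter while leaving the per-fold weight w_pos = N_neg/N_pos (computed
on pre-SMOTE labels, otherwise it would trivially be 1/ratio) with real
work to do; both knobs are configurable because neither the target ratio
nor the mechanism ordering is externally fixed. The weight enters the
boosted log-loss exactly as an instance weight on positives — for
log-loss, scaling the positive-class gradient and hessian by w_pos and
weighting the instance are the same operation, so no tree internals are
re-derived (a unit test pins the algebra).

The decision threshold maximizes Youden's J over pooled out-of-fold
validation scores from an inner stratified 5-fold CV on the training
partition. The candidate set is the unique scores plus {0, 1}; midpoints
between adjacent scores are omitted because they produce identical
confusion matrices (they only relabel the same cut), and ties are broken
toward the smallest threshold, encoding the safety-first preference for
sensitivity. Ensemble defaults: learning rate 0.01, 500 trees, maximum
depth 8, row subsample 0.7, column subsample 0.8, single thread, seeded —
predictions are reproducible bit-for-bit and survive serialization
round-trips.

**Per-subject calibration.** The "freeze the feature extractor, update the
head" idea is a neural-network notion; for a tree ensemble we reinterpret
it as: keep the generic ensemble, append a small number of strongly shrunk
trees (25 trees, shrinkage 0.05) fitted to the subject's calibration
windows, and re-run the Youden search on the calibration scores. Either
step is skipped when the calibration labels are single-class — adapting a
decision threshold with no positive (or no negative) examples is
unidentifiable, and we prefer a guarded no-op over a fabricated update.
Calibration windows are the chronologically first 30 of the subject and
are never reused as test windows.

## 6. The synthetic cohort generator

The generator is the package's test oracle: every downstream stage is
validated against quantities the generator knows exactly (R-peak times,
scripted fixation events, empirical tachogram HRV, per-window regime
parameters).

**Tachogram.** RR_i = mean_rr + lf_amp·sin(2π·0.10·t) +
hf_amp·sin(2π·0.25·t) + N(0, rmssd_target/√2). The two tones sit at the
LF/HF band centres, so band powers — and therefore LF/HF — are directly
controlled by the amplitude pair. A direct sinusoid-plus-noise tachogram
was chosen over integral-pulse models because it makes the spectral
ground truth trivial. The parameter pair (sdnn_target, rmssd_target)
overdetermines this model; the noise scale derives from rmssd_target and
sdnn_target is carried as the preset's nominal total variability.

**ECG.** A Gaussian-kernel PQRST template (P, Q, R, S, T amplitudes
0.12/−0.12/1.0/−0.18/0.35 mV at −180/−22/0/+22/+170 ms) is stamped at
each beat time, snapped to the sample grid; additive 0.2 Hz baseline
sinusoid, 50 Hz powerline sinusoid and white noise complete the trace.
Beats are kept 0.35 s clear of the trace edges so every template fits
completely — edge-clipped beats are not legitimate detector misses.

**Gaze.** Fixation targets follow a Markov chain over AOI cells mixing a
uniform chain (weight = aoi_concentration) with a local
self-and-neighbours chain, so one scalar sweeps the scanpath from
tunnelled (low entropy) to uniform (entropy → log2 K). Fixation durations
are log-normal; saccades are ballistic at 200°/s — far above the 30°/s
threshold by construction so I-VT labels are unambiguous; pupil diameter
is an AR(1) process (φ = 0.98); blinks are Poisson events with log-normal
durations inside 75–500 ms and long closures (> 500 ms, median 900 ms)
arrive as a separate rare Poisson stream to drive PERCLOS.

**Cohort structure and presets.** Each subject receives once-drawn
log-normal multiplicative baselines: SD 0.30 on mean RR, pupil base and
fixation duration — resting heart rate and fixation style vary strongly
between individuals, and this is precisely what limits cross-subject
transfer — and SD 0.25 on blink duration and closure rate.
Scenario states are assigned by exact proportional counts (77.0% alert,
18.5% transitional, 4.55% fatigue — the window-level mix that yields the
~17:1 post-exclusion imbalance) shuffled uniformly across all
subject-scenarios, and the SP-7 score is drawn within the state category
with realistic skew (alert mass concentrated at 1–2; fatigue at 5). The
regime parameters for a scenario interpolate linearly between the alert
and fatigue presets at w = (SP-7 − 1)/6 **plus scenario-level Gaussian
jitter (SD 0.20)** — the subjective rating tracks physiology only
loosely, and without this decoupling every protocol saturates at
accuracy 1.0 and no cross-subject generalization gap can exist. Eyelid
closure behaviour (closure rate and blink duration) follows a
**saturating √w response**: steep across the alert range, where it
carries the rank correlation between rating and PERCLOS over the mostly
alert windows, and flattening toward deep fatigue. The alert/fatigue
presets encode the expected fatigue phenomenology (slower heart rate,
higher RMSSD, lower LF/HF, slower blinks, frequent long closures,
longer fixations, lower gaze entropy, unstable pupil), with the
strongest couplings deliberately placed on the eyelid-closure and
cardiac sides: in the study this package models, the cardiac features
were the more transferable discriminators and the non-PERCLOS ocular
features the weaker ones, so fixation duration, scan entropy, pupil
variability and blink rate shift only mildly between regimes. Emitted
cohorts reach a pooled SP-7 ↔ PERCLOS Spearman r ≈ 0.5, well short of
the r ≈ 0.9 reported on real data: Poisson closure counts put an
irreducible floor on per-window PERCLOS noise, and pushing the coupling
high enough to match would make the ocular modality alone a
near-perfect classifier, which the same study's modality ablation
rules out.

**What the generator does not emulate.** Real 12-lead ECG morphology and
arrhythmias; video-based eyelid aperture (hence the PERCLOS proxy);
temporal autocorrelation of fatigue across a session (fatigue scenarios
are shuffled, not accumulated toward shift end); head movement,
illumination artifacts, electrode motion artifacts beyond stationary
noise; scenario semantics (traffic complexity). Passing tests on this
cohort therefore demonstrate the correctness of the algorithms and the
direction of the modelled effects, not field performance on real
operators.

## 7. Evaluation protocols and problem sizes

Protocol A is a stratified 80:20 split (default seed 42) with the inner
5-fold CV supplying threshold-selection scores; Protocol B is LOSO with
per-fold threshold selection inside the N−1 training subjects; the
calibration experiment evaluates each held-out subject's windows after
its first 30, before and after calibration on those 30. The ablation
harness crosses modality subsets (8-D eye, 4-D ECG, 12-D fusion) with
imbalance strategies (none / weight-only / SMOTE-only / hybrid) under
stratified 5-fold CV; only the hybrid strategy moves the threshold, the
others hold 0.5, and "none" also sets w_pos = 1. Model comparisons use
the classic Friedman chi-square on within-block average ranks with the
Nemenyi critical difference qtukey(0.95, k, ∞)/√2 · √(k(k+1)/(6b)).

The package's own experiments (tests and the acceptance script) run on
cohorts of 8 subjects × 12 scenarios × 240 s (≈ 384 windows, ≈ 39
labelled windows per subject) — large enough for LOSO, the ablations and
the 30-window calibration protocol to be meaningful, small enough to
generate and process in about a minute per seed; directional findings are
asserted as majorities over five seeds. The generator's defaults
(36 × 10 × 600 s) reproduce the full study geometry and are used where
signals are not needed (label accounting, imbalance ratio).

## 8. Known limitations

* The SP-7 ↔ PERCLOS concordance of the synthetic cohorts (r ≈ 0.5–0.8)
  undershoots the strongest reported real-data values; driving it higher
  would require near-deterministic closure behaviour that then saturates
  every classifier.
* A 60-s window cannot resolve the lower LF band edge; LF/HF from such
  windows is noisy by construction.
* The calibration experiment inherits the guarded no-op: subjects whose
  first 30 windows are single-class are left uncalibrated, so cohorts
  with very low per-subject fatigue prevalence show small average
  calibration gains.
* Threshold moving on small validation pools (tens of windows) has high
  variance; the smallest-threshold tie-break is deliberately
  sensitivity-greedy and can cost specificity on new subjects.
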