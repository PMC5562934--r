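---
title: "Exercise recognition from IMU time-series images: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exercise recognition from IMU time-series images: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(imuvision)
```

## The problem and the two classification routes

A lumbar-worn inertial measurement unit (IMU) streaming tri-axial
accelerometer (±16 g, m/s²) and gyroscope (±500 °/s) data at 51.2 samples/s
records a subject performing sets of lower-limb exercises: bodyweight squat
(SQ), bodyweight lunge (LUL), barbell deadlift (DL), single-leg squat (SLSL)
and tuck jump (TJ). The task is to label each completed repetition with its
exercise class.

`imuvision` implements two routes to that label:

1. **The feature-free (machine-vision) route.** Each repetition is rendered
   as a small fixed-scale image of its six raw signals, and an image
   classifier — a frozen convolutional embedding backbone plus a retrained
   softmax output layer — learns the classes directly from the plots. The
   premise is that the waveform morphology visible in the plots is distinct
   enough per exercise that no engineered features are needed.
2. **The feature-based comparator.** The conventional pipeline: 18 derived
   signals × 19 engineered features = 342 values per repetition, classified
   by a 400-tree random forest under leave-one-subject-out cross-validation
   (LOSO-CV).

Both routes share the same preprocessing and segmentation front end.

## Preprocessing: low-pass filtering

All channels are low-pass filtered with an order-8 Butterworth design at
$f_c = 20$ Hz (`filter_config()`), since the movement content of these
exercises sits well below 20 Hz while sensor noise does not. The discrete
filter comes from the bilinear transform with prewarping
(`signal::butter`), so its magnitude matches the analog prototype
$|H(f)| = (1 + (f/f_c)^{2n})^{-1/2}$ throughout the passband and exactly
at the cutoff (−3 dB). Two numerical choices matter:

* **Zero-phase default.** Segmentation hinges on zero-crossing and peak
  *locations*; a causal pass would delay them by a frequency-dependent lag.
  The default therefore applies the filter forward and backward
  (amplitude response $|H(f)|^2$, zero lag); `mode = "causal"` provides the
  single-pass variant.
* **Edge handling.** The forward-backward pass uses odd-reflection padding
  (up to 100 samples per end) and first-sample steady-state initialisation,
  so series with a non-zero baseline (gravity on `acc_z`, unit `quat_w`) do
  not acquire start-up transients. Both passes are exactly linear, and a
  constant series passes through bit-faithfully to within 1e-9.
* **Direct form, not second-order sections.** At the normalized cutoff used
  here ($20 / 25.6 \approx 0.78$) the order-8 direct-form polynomial is
  numerically benign; the implementation is validated against the analytic
  magnitude response to better than 0.1% rather than against any particular
  coefficient layout. At *low* normalized cutoffs a cascaded-biquad
  realisation would be preferable.

One caveat is inherent to any bilinear design: in the transition band the
digital response is *steeper* than the analog formula (frequency warping),
deviating by a few percent within 16–25 Hz. Validation tones are therefore
placed in the passband and at the cutoff, where the analytic formula is the
correct reference.

## Segmentation: peaks and adjacent zero crossings

Repetitions are detected on the gyroscope channel with the largest
peak-to-peak range (`select_channel()`; "largest amplitude" is read as
peak-to-peak, and exact ties resolve to canonical channel order). On that
channel, peaks are local maxima above `min_peak_height` (default 0.5) times
the maximum absolute value, separated by at least `min_peak_separation_s`
(default 1.0 s — about half a repetition; both are artifact defaults since
no peak-detection parameters are pinned by the protocol). Each peak is then
bracketed by its adjacent zero crossings.

Discrete conventions, chosen for determinism:

* Sample indices are 0-based and epochs are half-open `[start, end)`.
* A zero crossing is a sign change between consecutive samples; a value
  within `1e-9 × max|signal|` of zero counts as a crossing sample
  (so `sin(π)` computed in floating point is a crossing). The epoch includes
  a leading zero sample and excludes a trailing one: one sampled sine period
  at `fs = 50` segments as `(start 0, peak 12, end 25)`.
* A peak with no preceding (following) crossing clamps to the series start
  (end).
* Peaks are sought on the signed signal, positive lobes only;
  `use_abs = TRUE` serves signals with negative-dominant lobes.

Each epoch is then linearly interpolated onto `resample_length = 250`
uniformly spaced points (endpoints preserved exactly; resampling at the
native length is the identity).

## Image encoding

Each resampled repetition becomes one image of six vertically stacked
panels in fixed order with fixed symmetric y-limits — `gyro_x` ±250 °/s,
`gyro_y`/`gyro_z` ±100 °/s, `acc_x` ±3 m/s², `acc_y`/`acc_z` ±15 m/s² —
with no axes, ticks or labels, written as 470×470 JPEG files (quality 0.95;
PNG available). Because the limits are absolute, amplitude is informative
across images, and out-of-range values are **clipped** to the panel border
rather than rescaled.

Rendering uses the package's own rasterizer (vertical-span polyline joins,
2 px line, blue on white) rather than a plotting device, making the pixel
array a *pure function* of the epoch values and the spec: identical inputs
give bit-identical arrays, which the determinism tests assert at byte
level. Line styling beyond the pinned y-limits, size and axis hiding is not
prescribed by the protocol, so it is fixed here once for reproducibility;
pixel-exact appearance relative to any other plotting stack is explicitly
not a goal.

## Transfer-learning classifier

The image route follows the transfer-learning recipe: a fixed embedding
backbone computes a "bottleneck" vector per image, and only the final
softmax layer is trained on the new classes.

* **Backbone.** The desk-scale default (`tiny_cnn_backbone()`) is a frozen
  random-filter convolutional network: ink-intensity grayscale → 10×10
  block mean-pool (470 → 47) → 8 5×5 convolutions + ReLU + 4×4 pooling →
  8 3×3 convolutions + ReLU + 2×2 pooling → 128-dimensional L2-normalised
  embedding. The filters are drawn once from a seeded Gaussian and never
  trained — random convolutional features are an established embedding
  family, the backbone contract only requires a deterministic image →
  embedding map, and freezing it mirrors the transfer-learning premise that
  the pretrained network is left intact. Any other backbone satisfying the
  same contract (for example a large pretrained network) can be plugged in.
* **Bottleneck caching.** Embeddings are cached on disk keyed by backbone
  name and image content hash, so retraining sweeps never recompute them.
* **Retrained head.** `retrain_final_layer()` fits a multinomial softmax by
  mini-batch gradient descent on cross entropy (desk defaults: 1,000 steps,
  batch 32, learning rate 0.5, 10% validation split; the full-scale 96,000
  step schedule is kept as `preset = "study"`). The split and batch order
  are fully seeded, so curves are reproducible; logged curves carry
  training accuracy, validation accuracy and cross entropy, whose
  train/validation gap is the overfitting diagnostic. Training runs the
  fixed number of steps; on the separable synthetic embeddings convergence
  is fast and no early stopping is applied.

## Feature-based comparator

`derive_signals()` extends the six raw channels with magnetometer,
acceleration/rotation magnitudes, orientation quaternion and Euler angles
(18 signals). `compute_features()` computes per signal epoch: mean, RMS,
standard deviation, kurtosis, median, skewness, range, variance, max, index
of max, min, index of min, energy, 25th/75th percentiles, level crossing
rate, Higuchi fractal dimension, and the variances of the wavelet
approximation and detail coefficients — 19 features, 342 per repetition.
Conventions the counting forces or the protocol leaves open:

* **Wavelet.** Daubechies-4 (8-tap) to level 7 under *periodization*, which
  keeps level 7 valid for 250-sample epochs; the implementation reproduces
  PyWavelets' periodized DWT coefficients and is frozen against it in the
  tests. One feature is the variance of the level-7 approximation, one the
  variance of all detail coefficients pooled across levels 1–7 — per-level
  variances would inflate the count to 26 and break the 19 × 18 = 342
  arithmetic.
* **Level crossing rate** counts strict sign changes about the epoch mean,
  divided by `length − 1`.
* **Higuchi fractal dimension** uses `k_max = 10` (reduced automatically on
  very short series); energy is the unnormalised sum of squares; index
  features are 0-based and unnormalised.
* Features are computed on the resampled (250-sample) epochs for
  consistency with the image route; `segmenter_config(resample_length = NA)`
  exposes native-length epochs for sensitivity checks.
* A constant epoch has undefined kurtosis/skewness; both return 0 with a
  warning.
* Time-reversing an epoch leaves every *order-free* feature (all moments,
  quantiles, energy — including skewness, which depends only on the sample
  multiset), the level crossing rate and the Higuchi dimension invariant;
  only the index features (which mirror to `n − 1 − idx`) and, mildly, the
  periodized wavelet variances are order-sensitive. The property tests
  encode exactly this set.

The comparator classifier is a 400-tree random forest
(`randomForest`), evaluated by LOSO-CV: each subject is held out in turn,
predicted by a forest trained on all other subjects, and the pooled
predictions form one confusion matrix.

## Evaluation

`confusion_report()` produces the confusion matrix, accuracy
(trace/total, exact in integer arithmetic before formatting; percentages
print to 2 decimals), and one-vs-rest per-class sensitivity and
specificity — the standard multi-class reading of specificity. Reports
round-trip losslessly through JSON, with optional training curves attached.

## The synthetic-data generator

The laboratory dataset behind the original study (82 subjects) is not
deposited, so the package generates its own study conditions
(`synthetic_config()`); the generator is first-class, tested code, and its
defaults are the conditions under which all recovery results are stated:

* 10 repetitions per set, mean repetition 2.8 s (scaled per class: single-leg
  squats slower, tuck jumps faster), gaps of 1.2 s, at 51.2 samples/s.
* Class-distinct parametric templates on the six raw channels: a biphasic
  dominant lobe for SQ, an asymmetric early-peaked lobe for LUL, a single
  smooth lobe for DL, a low-amplitude long lobe on `gyro_y` for SLSL, and a
  narrow high-amplitude burst for TJ — realising, controllably, the premise
  that per-class waveform morphology is distinct. Amplitudes sit inside the
  fixed plotting ranges, and the dominant gyroscope channel returns to zero
  between repetitions so the segmentation contract is satisfiable.
* Per-subject variability: one multiplicative amplitude factor
  (s.d. 0.15) and one tempo factor (s.d. 0.10) per subject, consistent
  across that subject's exercises — this is what makes LOSO-CV meaningful —
  plus ±8% per-repetition duration jitter.
* Additive i.i.d. Gaussian noise per channel family; the default
  (gyroscope 2 °/s, accelerometer 0.15 m/s², magnetometer 0.2 µT,
  orientation 0.005 rad) is representative of a consumer-grade IMU at this
  bandwidth and is low relative to movement amplitudes.
* Extended signals are generated *directly* as smooth functions of an
  orientation excursion angle (quaternions exactly unit-norm; magnitudes
  exactly the Euclidean norms of the noisy axis channels); estimating
  orientation from raw IMU data by sensor fusion is out of scope.
* Everything derives deterministically from one integer seed; each
  recording's ground-truth `(start, peak, end)` per repetition is computed
  from the clean dominant channel by the same crossing convention the
  segmenter uses.

**What passing on this generator does and does not show.** The templates
make between-class differences large and within-class variation
well-behaved, so near-perfect recovery here demonstrates that the pipeline
machinery is correct (segmentation boundaries within ±2 samples at zero
noise; held-out image-route accuracy and LOSO forest accuracy ≥ 0.90 at
study scale), *not* that comparable accuracy would be reached on real
recordings, where waveforms drift, repetitions blend, and no statistical
description of the real signals is available to calibrate against. The
published headline accuracies on the laboratory dataset are likewise not
reproducible here and are never used as expected values.

## Problem sizes used in the checks

The shipped checks run at a deliberate desk scale: 10 subjects × 5
exercises × 10 repetitions (≈ 500 epochs) for the two end-to-end recovery
results, 1,000 training steps for the softmax head, 25 single-recording
seeds for segmentation recovery, and 2,048-sample tones for the filter
oracle. These sizes were chosen so the whole suite exercises every stage
end-to-end in a few minutes on one CPU while keeping all acceptance margins
wide.

## Known limitations

* The generator is phenomenological, not a biomechanical simulation; it
  emulates morphology, tempo and noise, nothing more.
* Only the final layer is ever trained; fine-tuning earlier layers, data
  augmentation and image processing are deliberately excluded.
* The desk backbone's random features suffice for the synthetic classes but
  are far weaker than a pretrained network on real plots.
* JPEG output is lossy; determinism guarantees are stated on the
  pre-encoding pixel grid (and hold end-to-end for PNG).
* Segmentation assumes one exercise per recording with positive dominant
  lobes; mixed-activity streams are out of scope.
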