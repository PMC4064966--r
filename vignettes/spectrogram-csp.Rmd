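---
title: "Single-channel motor-imagery classification with spectrogram CSP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-channel motor-imagery classification with spectrogram CSP}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stftcsp)
```

## The problem

Motor imagery — mentally rehearsing a movement without executing it —
modulates the sensorimotor mu (8–13 Hz) and beta (16–25 Hz) rhythms:
imagery of a movement typically *desynchronises* the contralateral rhythms
(ERD, a band-power drop), with rebounds and surround effects that
*synchronise* them elsewhere (ERS). Multichannel BCIs decode these patterns
with common spatial patterns (CSP): linear filters over channels that
maximise the variance of one class relative to another. With one electrode
there are no channels to combine, so plain CSP is unusable.

`stftcsp` implements the spectral channel-expansion approach. A short-time
Fourier transform converts the single channel into an F × T magnitude
matrix **E**; its frequency rows are treated as virtual channels, and CSP is
applied to **E** exactly as it would be to a multichannel trial. Class
information that lives in *which frequency bands* change power after the
cue is then exactly what CSP's variance-ratio filters pick up.

## Pipeline and parameters

**Epoching** (`extract_window`). Trials are 7 s at 250 Hz with the imagery
cue at 3 s. Time-to-sample mapping is 0-based and half-open
(index = `floor(t * fs)`), so adjacent windows such as [3,4) and [4,5) share
no sample and a 1-s window is exactly 250 samples. Trials shorter than the
requested window are an error, never padded: padding would silently change
the spectrogram's frame count. The pipeline default window is the full
imagery period [3, 7) s; the four one-second windows are kept as the
evaluation surface of `eval_grid` (see *Design choices*).

**STFT** (`stft_magnitude`, `band_restrict`). Segments of 100 samples
(0.4 s), symmetric Hamming taper of the same length, zero-padded to
128-point FFTs, hop 50 samples (50% overlap). Bin centres are
k·fs/128 ≈ k·1.953 Hz; the frame count is ⌊(N − 100)/50⌋ + 1, i.e. T = 4
frames for a 1-s window and T = 16 for the full 4-s imagery period. The
one-sided *magnitude* spectrum feeds CSP: the covariance algebra needs a
real matrix, and magnitude (rather than power) keeps the amplitude scale
linear. Restricting to 8–30 Hz inclusive keeps bins k = 5…15, F = 11
virtual channels spanning 9.77–29.30 Hz. No detrending is applied within
segments; the targeted recordings are already 1–50 Hz band-passed.

**OVR-CSP** (`class_covariance`, `whitening`, `fit_ovr_csp`). Per trial,
the spatial covariance E·Eᵀ is divided by its trace — standard CSP
practice that removes per-trial amplitude scale and makes the end-to-end
result invariant to global gain — and averaged within class. The composite
R = ΣR_k is whitened, P R Pᵀ = I; because the whitened own-class and
rest-class covariances sum to the identity, one symmetric eigendecomposition
per class simultaneously diagonalises both with complementary eigenvalues
(λ_own + λ_rest = 1, each in [0, 1]). Rows of W_k = Bᵀ P are sorted by
descending own-class eigenvalue and the filter W̃_k takes the first and
last m rows. The test suite verifies this whitening route against the
directly solved generalized eigenproblem R_k v = λ R v on random PSD
quadruples.

**Features and classifier** (`variance_features`, `grid_search_cv`). Each
filtered matrix Z_k = W̃_k E is summarised by row-wise sample variances over
frames (denominator T − 1, raw — not log-transformed), concatenated across
the four classes to a 1 × 8m vector. An RBF C-SVC (libsvm via `e1071`,
one-vs-one multiclass voting) is tuned by grid search over the conventional
coarse grid C ∈ 2^{−5,−3,…,15}, γ ∈ 2^{−15,−13,…,3}, with mean CV accuracy
as the criterion and ties broken towards smaller C then smaller γ. Features
are affinely mapped to [0, 1] per feature, with the map fitted on training
folds only — variance features of different CSP rows differ by orders of
magnitude, which an RBF kernel handles poorly unscaled.

**Protocol** (`cv_protocol`, `run_pipeline`). Stratified k-fold CV
(default 10 folds), optionally repeated with re-drawn partitions. Within
*each* outer training fold the CSP filters are re-fitted, features rebuilt,
and (C, γ) re-searched with an inner 5-fold CV; the held-out fold only ever
meets the final fitted model. The suite checks directly that corrupting
held-out trials leaves the fitted filters bit-identical.

## The synthetic generator

`generate_trials` emulates the statistical structure the method assumes:

- a 1/f^β background (β = 1) built by spectrally shaping white noise,
  standard deviation 10 µV;
- per profiled band, band-limited Gaussian noise (FFT masking) at baseline
  standard deviation 10 µV, multiplied by an amplitude envelope that moves
  from 1 to 1 + depth at the cue over a 250 ms raised-cosine ramp. Power
  therefore changes by (1 + depth)²; the modulation affects amplitude only,
  never phase, so nothing is phase-locked to the cue;
- identical pre-cue statistics across classes; class identity lives
  entirely in the post-cue depths.

The default class code assigns each class a *sign pattern* of depth-0.7
modulations over the two rhythms: (mu, beta) = (−,−), (−,+), (+,−), (+,+)
for classes 1–4. This is a stylisation of real effects (bilateral hand-ERD
with and without beta rebound, surround ERS during foot/tongue imagery);
its purpose is that every pair of classes differs by 2 × depth in at least
one rhythm, so four-class separability from a single channel is engineered
into the data by construction. The baseline oscillation amplitude equals
the background amplitude, which puts clear mu/beta peaks on the 1/f
spectrum, as in resting sensorimotor recordings with prominent idle
rhythms.

What the generator does *not* emulate: volume conduction and electrode
geometry (no far-field structure — "channels" differ only in simulation
seed), EOG/EMG artifacts (artifact flags exist purely to exercise the
exclusion path), non-stationary baseline drift, inter-trial rhythm
frequency variability, and phase-locked evoked responses. Passing tests
therefore demonstrate that the *pipeline* recovers engineered band-power
structure, not that real recordings carry such structure — on real data
the ceiling is far lower, as the published single-channel accuracies
(0.50–0.88 across electrodes and windows in the shipped benchmark grid)
show.

## Design choices

- **Default analysis window [3, 7) s.** A variance over T frames has
  relative noise ≈ √(2/(T−1)): at a 1-s window (T = 4) every feature
  carries ~80% noise and end-to-end accuracy on strongly separable
  synthetic data plateaus well below its information limit. The full
  imagery period gives T = 16 and robust recovery. The four 1-s windows
  remain available (and are the unit of the `eval_grid` surface); the
  acceptance script uses the 4–5 s window for its chance-level number.
- **STFT parameterisation.** Segment length 100 with zero-padding to 128
  was preferred over a 128-sample taper: the two readings are mutually
  exclusive, and only the former gives the zero-padding any meaning.
- **Magnitude, not power or complex coefficients**, enters the covariance:
  E·Eᵀ needs real entries, and squaring (power) would double the dynamic
  range that the downstream variance features then square again.
- **m beyond F/2.** The filter pairs overlap once 2m > F (m = 7 vs F = 11
  by default); duplicated rows are kept with a warning. Duplicate variance
  features are redundant but harmless to the margin-based classifier, and
  this keeps the full m = 1…10 sweep well-defined.
- **Ridge policy.** Whitening adds ε = 10⁻⁸ · trace(R)/F to the diagonal
  only when the smallest eigenvalue falls below ε — far below signal scale,
  recorded in the model.
- **Sign convention.** Each filter row's largest-magnitude entry is made
  positive, so results do not depend on eigen-solver sign choices.
- **"10×10-fold" cross-validation** is read as 10 independent repetitions
  of stratified 10-fold CV (`cv_protocol(10, 10)`); the hyperparameter grid
  is a separate, orthogonal loop. Pipeline-level defaults use a single
  repetition; repeats are for dispersion reporting.
- **Inner model selection** uses 5 folds (one repetition) per outer
  training fold — 110 grid points × 5 folds × 10 outer folds ≈ 5,500 SVM
  fits per pipeline run, a sensible cost/stability point for ~150-trial
  sets.
- **ANOVA conventions.** The electrode × window grid is analysed by
  classical fixed-effects two-way ANOVA with participants/datasets as
  replicates; the interaction is included only when there is more than one
  replicate per cell. A factor with zero between-group sum of squares
  reports F = 0, p = 1 rather than 0/0.

## Problem sizes in the test suite

Unit and property tests run on small fixtures built in code: random PSD
covariance quadruples up to F = 16 (100 instances per numerical contract),
synthetic sets of 5–8 trials per class with a reduced (C, γ) grid for
pipeline behaviour, 200-trial sets for generator calibration (spectral
slope within ±0.3, band-power ratio within 10%), and the full study
conditions — 40 trials per class, m = 7, coarse grid, stratified 10-fold
CV — for the end-to-end chance-level and parameter-recovery checks.

## Known limitations

- The generator's class code is spectral; it cannot represent classes that
  differ only spatially, which is precisely the regime where a single
  channel must fail.
- Variance features at 1-s windows rest on 3 degrees of freedom; per-second
  accuracies are accordingly noisy, matching the wide spread of the
  published per-window grid.
- `m` larger than F duplicates filters rather than extending them; there is
  no regularised or analytic-shrinkage CSP variant.
- The CLI and I/O handle delimited text with JSON sidecars only; native
  EEG container formats (GDF/EDF) are out of scope.
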