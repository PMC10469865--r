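---
title: "Methods: wavelet asymmetry analysis of EEG emotion processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet asymmetry analysis of EEG emotion processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hemiwave)
```

# The scientific question

Two classical accounts of emotional lateralization — right-hemisphere
dominance, and valence lateralization (left = positive, right = negative) —
predict systematic differences between homologous left/right scalp sites.
`hemiwave` operationalizes that question for four-emotion video protocols
(neutral, sad, fear, happy) on a 62-channel extended 10-20 montage: it
quantifies, per frequency band and symmetric channel pair, whether relative
oscillatory energy differs between hemispheres, and which of those
differences carry predictive information about the felt emotion across
subjects.

# Model and assumptions

## Features

Each trial is resampled to 200 Hz, band-passed 0.5–50 Hz and cut into
non-overlapping 4 s windows. Windows are decomposed with a six-level db2
DWT; at 200 Hz the dyadic levels align with the canonical bands (d2 gamma …
d6 delta). The feature is the natural log of the ratio of *relative* band
energies between the left and right member of each of 27 symmetric pairs:
135 features per window. Working with energy shares removes per-channel
scale; working with log-ratios makes the statistic antisymmetric under
hemisphere exchange and additive in log-energy.

Assumptions worth stating explicitly:

* the band↔level identification is only valid at fs = 200 Hz — the feature
  stage refuses other rates rather than silently mis-mapping;
* E_Total sums *all* seven components (d1…d6, a6), so content outside the
  named bands (0–1.56 and 50–100 Hz) dilutes every share equally;
* the level-6 detail is labeled delta (1.5625–3.125 Hz) even though the
  filter passes from 0.5 Hz; delta content in 0.5–1.56 Hz lands in a6 and is
  deliberately not counted — we implement the convention as printed rather
  than "correcting" it.

## Statistics (Experiment 1)

Per (pair, band, emotion) cell, segments are pooled across subjects and a
two-sided Wilcoxon signed-rank test asks whether the log-difference
distribution is symmetric about zero; η is the cell median. The family is
all 540 cells and Bonferroni correction is applied jointly
(0.05/540 ≈ 9.26e-5). Pooling at segment level (rather than subject means)
is a choice: per-emotion medians over pooled segments are what the matrix
display summarizes, and the test's validity under the null does not depend
on the pooling unit. Zeros are discarded (Wilcoxon's rule); the exact
distribution is used for n ≤ 25 tie-free samples, otherwise a normal
approximation with tie and continuity corrections.

## Classification (Experiment 2)

One binary logistic regression per emotion (one-vs-all), elastic-net
penalized, fitted without intercept so predictions depend only on the
features. Subject independence is enforced by leave-one-subject-out CV;
within each training set, hyperparameters (φ l1-ratio over 0…1 by 0.1; C
inverse strength over 10⁻³…10², 66 combinations) are chosen by group-aware
3-fold inner CV maximizing validation AUC-ROC, ties resolved toward
stronger then smoother regularization (smaller C, then smaller φ). ANOVA-F
selection (p < 0.05) and z-scoring are fitted on training rows only, once
per outer fold — selection inside the fold avoids the leakage that a single
global selection would introduce (the source description is ambiguous on
this point; we chose the leak-free reading). Unselected features are
embedded as zero coefficients, so every fold produces a full 135-vector and
fold averages are well defined.

C follows the inverse-strength convention (larger C = weaker penalty),
mapped to the coordinate-descent scale as λ = 1/(nC). Coefficients are
averaged on the standardized-feature scale; interpretation uses only signs
and relative magnitudes, which positive per-feature rescaling preserves.

## Interpretation and external validation

The averaged coefficient at pair (x, y), band b expands to +ω̄ on x and −ω̄
on y; the expansion reproduces the linear predictor identically (asserted
to 1e-10 in tests), so the channel map is not an approximation but a
re-indexing. Maps are normalized per emotion by the maximum absolute value
(chosen because it preserves sign and relative magnitude; the alternative —
global normalization across emotions — would couple unrelated models).
External validation applies ω̄ as a *fixed* model: external features are
standardized with the training dataset's pooled statistics (a fixed model
requires a fixed input transform; using external statistics would leak),
scores come from the logistic link, and AUC-ROC is reported per external
subject with "above chance" counted inclusively at 0.5.

# The synthetic world

The generator emulates the structure the analysis assumes, not physiology:

* **Composition.** Each channel is a sum of five band-limited stochastic
  oscillations, a 1/f broadband background over 0.5–100 Hz (exponent 1 by
  default — the classic EEG spectral slope), and a "rest" component confined
  to the unnamed a6 level.
* **Wavelet-domain oscillations.** At the 200 Hz fast path, band
  oscillations are drawn as random db2 coefficients at the band's own
  level. This is deliberate: db2's 4-tap filters leak roughly a quarter to a
  third of a brick-wall band component's energy into adjacent levels, so
  Fourier-masked noise would attenuate a planted 0.6 log-effect to ≈ 0.33
  as measured by the feature stage. Realizing the oscillations in the
  analysis basis makes planted energy gains land exactly where the features
  measure, at the cost of some spectral spread beyond the nominal interval —
  an acceptable trade, since real EEG rhythms are narrowband but the
  analysis itself is wavelet-domain. The standalone probe generator
  (`generate_band_limited_component`) defaults to the Fourier method, whose
  output is 100% spectrally in-band with exact RMS.
* **Planted effects.** An effect (emotion, band, pairs, L) multiplies the
  targeted band's component *energy* by e^{+L/2} on left and e^{−L/2} on
  right channels, so the pair log-energy-ratio has mean L. The rest
  component absorbs the difference per channel, keeping totals
  hemisphere-symmetric (otherwise every untargeted band would inherit a
  spurious shift of order L·w_b). The background's expected in-band energy
  is subtracted from each band's target so it does not dilute the ratio.
* **Subject variability.** One log-normal gain per subject × band
  (sd = `subject_sd`, default 0.2), shared across that subject's trials and
  both hemispheres — it therefore moves band *profiles* between subjects
  (making LOGO transfer non-trivial) without biasing any pair ratio.
* **Defaults.** Band profile weights 0.28/0.21/0.21/0.16/0.14
  (delta…gamma, a typical resting posterior-dominant distribution), noise
  weight 0.10, rest weight 0.12, total 30 µV RMS, 120 s trials in the
  SEED-IV/V-style layouts (15×3×24 and 16×3×12 trials). These are fixed
  choices of the stated world, not tuning knobs.

**What a green test establishes.** Calibration (planted 0.6 recovered
within 0.1; untargeted cells within 0.05 of zero — measured 0.58–0.59 and
< 0.01 generator→features), recovery (planted 0.8 → significant cell with
correct sign, LOGO AUC > 0.9, top-ranked averaged coefficient, fixed-model
transfer AUC > 0.85) and null control (family-wise false-flag rate ≤ 0.05,
chance-level AUC) validate the *pipeline's* correctness. They say nothing
about artifacts, non-stationarity (real ~2-minute clips likely redistribute
activity over time; effects here are stationary within a trial), volume
conduction, or any physiological claim.

# Numerical choices

* **DWT boundary.** Zero-pad to the next multiple of 2^levels, then exact
  periodized orthonormal steps. Pure periodization cannot take 800 samples
  through 6 levels (odd length at level 5); with padding, Parseval holds to
  machine precision for any length and reconstruction is exact.
* **Butterworth order 4, forward–backward.** Zero phase avoids shifting
  wavelet energies; step-response initial conditions make constant inputs
  settle immediately (DC rejection ~1e-11). Coefficients validated against
  an independent reference implementation during development.
* **Resampling.** Windowed-sinc FIR (10·factor+1 taps, Hamming, cutoff at
  90% of the target Nyquist) followed by integer decimation; 1000→200 Hz is
  exact. Upsampling and non-integer ratios are refused.
* **Epsilon floor 1e-12** on relative energies inside the log: band-passed
  segments can have numerically zero unnamed-band energy; the floor keeps
  all 135 features finite without materially moving any realistic value.
* **Wilcoxon** exact for n ≤ 25 tie-free (psignrank), else normal
  approximation with tie and continuity corrections; W reported as the
  smaller rank sum.
* **AUC-PR as average precision** (step-wise) rather than trapezoidal
  interpolation, which is optimistic for PR curves; AUC-ROC via the
  rank-sum estimator (exact trapezoid with tie handling).
* **Degenerate cases.** No feature selected → null model with 0.5 scores
  and a warning; no predicted positives → PPV/F1 recorded as 0 with a
  warning; single-class held-out subjects → AUCs recorded as missing, never
  fabricated; all-zero segments and single-class fits are errors.
* **Determinism.** One user seed fans out to per-stage/per-trial streams by
  a rolling-hash derivation; identical (spec, seed) reproduce datasets
  bit for bit, and glmnet's coordinate descent is deterministic given the
  data.

# Known limitations

* The a6-level rest component is partially removed by the 0.5 Hz high-pass,
  so after full preprocessing the hemisphere-balancing is imperfect: with a
  planted effect, untargeted cells shift by about −0.04 (within the null
  tolerance, but visible). Calibration properties are therefore asserted on
  generator→feature runs; pipeline-level criteria use thresholds robust to
  this residual.
* The planted-effect magnitude as measured after band-pass filtering is
  mildly attenuated (0.8 → ≈ 0.68 median), since filtering reshapes the
  wavelet-domain components; sign and significance are unaffected.
* Non-200 Hz generation falls back to Fourier band synthesis, so calibrated
  effect recovery is only guaranteed on the 200 Hz fast path (the 1000 Hz
  native path exists to exercise the resampler).
* No artifact simulation (eye blink, EMG) and no advanced artifact removal;
  the band-pass is the only cleaning stage, as in the analysis being
  implemented.
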