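---
title: "Estimating respiration rate and SpO2 from single-channel PPG: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating respiration rate and SpO2 from single-channel PPG: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

A photoplethysmogram (PPG) measures blood-volume changes optically. Breathing
leaves three well-known imprints on the cardiac pulse train — baseline wander,
amplitude modulation, and frequency modulation, all at the respiratory
frequency `f_R = RR / 60` Hz — while blood oxygenation correlates with pulse
morphology. `ppgvitals` turns these observations into a supervised pipeline:
32 s windows of a single PPG channel are cleaned, delineated beat by beat,
summarized by a fixed catalog of 107 features, and mapped to respiration rate
(RR, breaths/min) and oxygen saturation (SpO2, %) by regression models trained
separately per target, because the two targets reward different features.

The pipeline is:

1. **Windowing** — 32 s frames with 50 % overlap (`segment_record`). A 32 s
   window holds enough breaths for RR in the 5–25 breaths/min range; shorter
   windows starve the spectral estimates, longer ones blur label changes.
   Trailing partial windows are dropped rather than zero-padded, since padding
   would bias every spectral feature.
2. **Denoising** — an order-6 Butterworth low-pass at 25 Hz applied forward
   and backward (`lowpass_zero_phase`), so the net phase response is zero and
   landmark timing is untouched.
3. **Motion-artifact removal** — variational mode decomposition
   (`vmd_decompose`, `remove_motion_artifacts`).
4. **Fiducial delineation** (`detect_pulses`, `beat_intervals`).
5. **Feature extraction** — exactly 107 features (`feature_catalog`,
   `extract_features`).
6. **Feature ranking** — GP-ARD, RReliefF, LASSO entry order, Laplacian score.
7. **Model fitting** under a 5-fold 60/20/20 protocol (`make_cv_plan`,
   `run_grid`) and the agreement metric suite (`eval_report`).

## Zero-phase filtering

"Order 6" is the per-pass design order; the forward–backward application
squares the magnitude response, doubling stop-band attenuation in dB. Edges
are handled by odd-reflection padding plus steady-state initial conditions in
the direct-form-II-transposed recursion. The pad is sized from the slowest
filter pole so the start-up transient decays below 1e-12 inside the pad —
about 120 samples for the default design, rather than a fixed small constant;
with a short pad the filter demonstrably fails its own zero-phase symmetry
property (filtering a time-reversed signal must equal the time-reversed
filtered signal to 1e-9). A constant segment passes through unchanged to
machine precision, which is the cheapest end-to-end check of the edge logic.

## Variational mode decomposition

VMD decomposes a signal into `K` band-limited modes by an ADMM iteration in
the frequency domain: each mode is updated by a Wiener-filter shrinkage
centered on its current center frequency, each center frequency moves to the
power-weighted mean frequency of its mode, and a dual variable (step `tau`)
enforces reconstruction. Defaults are `K = 5`, `alpha = 2000`, `tau = 0`,
`tol = 1e-7`, `max_iter = 500`, the regime recommended in the original VMD
literature; nothing in the estimation pipeline is sensitive to `K` as long as
the drift, respiratory and cardiac scales land in separate modes. The signal
is mirror-extended by half its length on each side before the transform, which
suppresses boundary splitting. Center-frequency initialization is uniform
starting at 0 — with PPG content concentrated below a few Hz, initializing the
lowest mode at DC matters: offset initializations leave the drift band
unclaimed and let two modes collapse onto the cardiac line.

**Artifact rule.** After decomposition of the *mean-removed* segment (the DC
level is not an artifact and must not inflate energy shares), the
lowest-center mode is removed only when it holds more than 30 % of the mode
energy **and** its center is below 0.1 Hz. The 0.1 Hz ceiling is deliberately
below the respiratory band's lower edge (0.083 Hz at RR = 5 breaths/min sits
close, but respiratory energy is spread across harmonics and modulation
sidebands, and in practice the respiratory mode centers above 0.1 Hz), so
respiratory information survives. The rule is conservative: on clean signals
nothing is removed, and the operation is idempotent.

## Fiducial delineation

The delineation scheme is this package's own design; the landmark vocabulary
(pulse foot/onset, systolic peak, dicrotic notch, diastolic peak, and the a–e
waves of the second derivative) is the field's standard one. Systolic peaks
are local maxima with prominence at least 30 % of the robust (5–95 %)
amplitude range, separated by at least `0.4 / f_HR` s, where `f_HR` is the
spectral peak in 0.7–3.5 Hz. The scheme favors systolic-peak recall because
the timing ratio `t1/tpi` and the amplitude statistics dominate the selected
feature sets. Onsets are minima between consecutive peaks; amplitudes are
measured relative to the preceding onset because filtering and VMD do not
guarantee a zero baseline. The notch and diastolic peak come from
zero-crossings of a Savitzky–Golay-smoothed first derivative (window 11,
order 3); when diastole is only a shoulder, the notch falls back to the
minimum of the smoothed second derivative and may remain undetected — such
beats contribute `NA`s that are excluded from the per-segment means rather
than imputed at beat level. Beats violating onset < peak < next onset or
non-positive amplitude are discarded and counted; fewer than 3 valid beats
marks the segment unanalyzable, and its fiducial-derived features become
missing while spectral and statistical features are still computed.

## The 107-feature catalog

The catalog is fixed, ordered, and contract-enforced at exactly 107 entries:

* **time (39)** — mean/SD/variance over beats of 13 quantities: systolic,
  diastolic and notch amplitudes, `t1`, `tpi`, `t1/tpi`, rise and fall time,
  widths at 25/50/75 % of the systolic amplitude, diastolic/systolic amplitude
  ratio, notch timing ratio.
* **derivative (22)** — mean/SD over beats of the a–e wave amplitudes, the
  ratios b/a, c/a, d/a, e/a, the aging index `(b−c−d−e)/a`, and the modified
  aging index `(b−e)/a`.
* **frequency (15)** — the maximum-magnitude frequency and its magnitude,
  parabolic-interpolated band peaks in the respiratory (0.05–0.6 Hz) and
  cardiac (0.7–3.5 Hz) bands, the top-3 spectral peaks (frequency and
  magnitude), three band-power ratios (respiratory, cardiac, harmonic
  3.5–10 Hz), spectral centroid and normalized spectral entropy — all from a
  Hann-windowed periodogram of the mean-removed segment.
* **statistical (31)** — 13 moments of the signal (mean, median, SD, variance,
  skewness, kurtosis, RMS, IQR, MAD, 16-bin base-2 Shannon entropy,
  zero-crossing rate, Hjorth mobility and complexity) plus 9 of the moment set
  on each of the first and second differences.

Conventions are stated because they are not universal: skewness and kurtosis
are population moments (kurtosis non-excess; a normal signal scores 3, a sine
1.5); the statistical group's SD/variance divide by `n`; beat statistics
across beats use the sample SD. The interpolated respiratory band peak is in
the catalog deliberately: at 32 s the raw periodogram bin width is 0.031 Hz
(≈ 1.9 breaths/min), and parabolic interpolation restores sub-bin resolution
so that the respiratory frequency — the physically exact encoding of RR — is
available to the models as a continuous quantity.

Missing features (undetected landmarks, unanalyzable segments) are
median-imputed from *training rows only* before model fitting.

## Feature ranking

* **GP-ARD** (`rank_gp_ard`): a zero-mean GP with squared-exponential ARD
  kernel plus noise, hyperparameters by marginal-likelihood maximization
  (L-BFGS-B, analytic gradients, 3 restarts on failure). Importance is
  `exp(−length_scale)` on standardized inputs. Two numerical guards matter:
  the log-length-scale box is capped at 6.5 so importances cannot underflow to
  exactly zero, and constant columns — whose ARD gradient is identically zero
  and would otherwise keep their (mid-ranked) initial value — are excluded
  from the fit and pinned to the smallest positive importance.
* **RReliefF** (`rank_relieff`): the regression Relief variant, k = 10
  neighbors, rank-based exponential influence decay with sigma = 50, all
  instances used (no subsampling) so the ranking is deterministic at this data
  scale.
* **LASSO** (`rank_lasso`): features ranked by the regularization-path lambda
  at which they first enter (glmnet coordinate descent), ties broken by
  coefficient magnitude at the path end.
* **Laplacian score** (`rank_laplacian`): unsupervised locality preservation
  on a heat-kernel k-NN graph (k = 5, bandwidth = median squared neighbor
  distance); lower scores are better and are negated into the common
  "descending importance" convention.

Default subset sizes are 8 features for RR and 11 for SpO2, mirroring the
benchmark layout this package follows; both are exposed, and `sweep_top_n`
provides the validation-set sweep for choosing them on new data.

## Models and the evaluation protocol

Five families with 19 preset variants: GPR (ARD, isotropic SE, Matern-3/2),
SVR (epsilon-insensitive; three RBF presets and one linear), ensembles (bagged
forests with 100/300 trees; boosted trees of depth 3/6), decision trees
(depths 2/4/8/16), and linear (OLS, ridge, LASSO, elastic net). The published
work this layout follows reports "19 variants" without itemizing them; this
zoo is the package's own reconstruction with the count matched.

`make_cv_plan` shuffles rows once by seed and splits them into five blocks;
fold *i* tests on block *i*, validates on the next block (cyclically), trains
on the rest — 60/20/20 with test sets partitioning the data. Everything
fitted — imputation medians, standardization, feature ranking, variant choice
— uses the fold's training rows only (validation rows only pick variants and
regularization strengths), and `leakage_audit` verifies this mechanically by
refitting with mangled test rows and asserting bit-identical fitted state.
Folds are drawn at the segment level to mirror the published protocol; with
50 %-overlapped windows from real recordings this lets adjacent windows of one
subject cross folds, a known optimism source, so an analysis of real data
should group folds by subject (the plan seed and construction make this a
small extension; the synthetic corpus has one independent subject per segment,
where the concern vanishes).

The metric suite reports MAE, RMSE, a baseline-relative
`R = 1 − MSE(model)/MSE(mean baseline)` (a coefficient-of-determination form),
the Pearson correlation (both are reported because published "R-values" are
often ambiguous between the two), twice the population SD of the error, and
Bland–Altman 95 % limits of agreement `bias ± 1.96 · SD(error)`. The
population (divide-by-`n`) SD is the default per the printed convention this
follows; the sample SD sits behind a flag.

## The synthetic generator

`generate_segment` renders a two-Gaussian (systolic + diastolic) beat template
on each beat's own period, with beat times from integrating the instantaneous
rate `hr · (1 + fm · sin(2π f_R t))`, amplitudes `1 + am · sin(2π f_R t_k)`,
an additive baseline `bw · sin(2π f_R t)`, white noise at a configurable SNR,
and Poisson-placed low-frequency artifact bumps. Defaults: `am = 0.10`,
`fm = 0.03`, `bw = 0.15` (within the ranges reported for respiratory
modulation of PPG), SNR 25 dB, artifacts 0.3/min of amplitude 1.5 and width
3 s; population ranges RR ∈ [5, 25] breaths/min, SpO2 ∈ [84, 100] %, HR ∈
[55, 95] beats/min drawn uniformly per segment. Template widths are specified
at a 1 s reference period and scale with the actual beat period, so morphology
stays physiological from 40 to 180 beats/min. The widths/offsets
(σ_sys = 0.07, σ_dia = 0.10, peaks at 30 % and 60 % of the period) are chosen
so a genuine dicrotic notch exists across the whole SpO2-linked morphology
range — the local-minimum criterion derived in the fiducials design.

The SpO2 link — diastolic/systolic ratio `ρ = 0.30 + 0.02·(100 − SpO2)` and a
systolic width scaling `1 + 0.01·(100 − SpO2)` — is a declared surrogate:
single-channel PPG cannot encode true ratio-of-ratios oximetry, and the
mapping exists to make SpO2 learnable-but-nontrivial for testing. Passing the
synthetic study therefore shows that the pipeline recovers the information the
generator encodes (respiratory modulation, morphology ratios) through the full
preprocessing/delineation/learning chain; it does not certify clinical
accuracy on real oximetry, where the morphology–SpO2 link is weaker and
confounded. The generator also omits arrhythmia, diseased morphologies
(dicrotic-notch loss), sensor saturation and non-stationary labels within a
window, so real-data performance must be established on real recordings.

Ground truth (`synth_truth`) carries programmed onset times (exact, because
each beat is rendered on its own period) and systolic peak indices (the
sample-grid argmax of the clean beat), which is what makes ±2-sample
peak-accuracy assertions meaningful.

## Problem sizes and numerical choices

The shipped synthetic study (`reproduce_synthetic`) uses a 1000-segment corpus
and runs the two-selector × two-family grid in about 5 minutes on one CPU;
the ranking/model stages dominate. Smaller corpora (60–150 segments) back the
module-level property tests. GP fits cap L-BFGS-B at 80 iterations with three
perturbed restarts on failure; the kernel adds 1e-10·σ_f² jitter to the
diagonal. VMD runs to a 1e-7 relative-change tolerance or 500 iterations, and
convergence failure is a flag, not an error, per mode-decomposition practice.
Degenerate inputs have defined behavior throughout: constant segments are
unanalyzable for delineation but still yield spectral/statistical features;
zero-variance columns standardize with scale 1, rank last in every selector,
and never enter models via LASSO; a constant truth vector makes the
baseline-relative R undefined and raises an error rather than returning a
misleading value.

## Reproducing the published benchmark

`reproduce_bidmc(path)` applies the exact published protocol to a local copy
of the BIDMC PhysioNet recordings and prints computed metrics beside the
published values. This is informational by design: the published corpus
involves a segment-quality screen and fold seeds that are not stated (53
records × 29 windows = 1537 raw windows versus the 1400 reported), so exact
agreement cannot be asserted, only inspected. No test or script downloads
anything.
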