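# ppgvitals

Respiration rate (RR) and blood oxygen saturation (SpO2) estimation from
single-channel photoplethysmogram (PPG) signals.

Continuous RR and SpO2 monitoring normally needs a chest band or a calibrated
two-wavelength pulse oximeter. A single PPG channel — the light-absorption
waveform behind every pulse oximeter and smartwatch sensor — already carries
both quantities: breathing modulates the pulse train's baseline, amplitude and
instantaneous frequency at `f_R = RR/60` Hz, and oxygenation correlates with
pulse morphology. `ppgvitals` implements a complete feature-engineering
pipeline that turns 32 s PPG windows into RR (breaths/min) and SpO2 (%)
estimates, for researchers working with ICU waveform archives (e.g. the
PhysioNet BIDMC collection) or wearable-quality recordings.

## The method

For each 32 s window (50 % overlap), the pipeline:

1. low-pass filters with an order-6 Butterworth at 25 Hz applied
   forward–backward (zero phase, so landmark timing is preserved);
2. removes motion artifacts by variational mode decomposition (VMD): the
   signal is split into K = 5 band-limited modes by an ADMM iteration, and the
   lowest-frequency mode is subtracted only when it is dominant (> 30 % of
   mode energy) and sub-respiratory (center < 0.1 Hz);
3. delineates every pulse — onset, systolic peak, dicrotic notch, diastolic
   peak, and the a–e waves of the second derivative;
4. computes a fixed catalog of exactly 107 features (beat timing/amplitude
   statistics such as the systolic-peak-time to pulse-interval ratio
   `t1/tpi`, second-derivative wave ratios, Hann-periodogram descriptors,
   statistical moments);
5. ranks features by Gaussian-process automatic relevance determination
   (importance `exp(-length_scale)`), RReliefF, LASSO path-entry order, or
   the Laplacian score, and keeps a top-n subset (defaults: 8 for RR, 11 for
   SpO2);
6. trains one of five regression families (GPR, SVR, ensembles, decision
   trees, linear; 19 preset variants) under 5-fold cross-validation with
   60/20/20 train/validation/test splits, separately for RR and SpO2;
7. reports MAE, RMSE, `R = 1 − MSE(model)/MSE(baseline)`, Pearson r, 2SD of
   the error, and Bland–Altman 95 % limits of agreement `bias ± 1.96·SD`.

A physiologically structured synthetic PPG generator (two-Gaussian beats with
respiratory AM/FM/baseline modulation and an SpO2-linked morphology surrogate)
makes every stage testable without downloading data and ships with ground-truth
landmark times for oracle-style accuracy checks.

## Worked example

```r
library(ppgvitals)

# one synthetic segment: 72 bpm heart rate, 18 breaths/min, SpO2 93 %
g   <- generate_segment(synth_config(hr_bpm = 72, rr_bpm = 18,
                                     spo2_pct = 93, seed = 42))
seg <- remove_motion_artifacts(lowpass_zero_phase(g$segment))
fid <- detect_pulses(seg)
fid
#> <pulse_fiducials>: 39 beats (f_HR ~ 1.19 Hz, 0 discarded)

v <- extract_features(seg, fid)
round(v[c("resp_peak_freq", "cardiac_peak_freq",
          "t1_tpi_ratio_mean", "dia_sys_ratio_mean")], 4)
#>     resp_peak_freq  cardiac_peak_freq  t1_tpi_ratio_mean dia_sys_ratio_mean
#>             0.3030             1.1969             0.3262             0.4491
```

The interpolated respiratory spectral peak sits at 0.303 Hz (18.2 breaths/min
— the programmed rate is 18), the cardiac peak at 1.197 Hz (71.8 beats/min),
and the diastolic/systolic amplitude ratio 0.449 reflects the SpO2-linked
morphology (the generator's ratio at SpO2 = 93 % is 0.44).

Running the full study on a 200-segment corpus:

```r
run <- reproduce_synthetic(n = 200, seed = 42, progress = FALSE)
run$headline$rr
#> <eval_report> n=200
#>   MAE  0.200 breaths/min   RMSE 0.440 breaths/min
#>   R    0.994    Pearson r 0.997
#>   bias -0.004 breaths/min  2SD 0.881 breaths/min  LOA [-0.867, 0.859] breaths/min
run$headline$spo2
#> <eval_report> n=200
#>   MAE  0.096 %   RMSE 0.120 %
#>   R    0.999    Pearson r 1.000
#>   bias +0.004 %  2SD 0.240 %  LOA [-0.232, 0.239] %
```

`run$rr$table` and `run$spo2$table` hold the full selector × model grid in the
benchmark-table layout (RMSE/MAE per combination). The headline rows use
GP-ARD top-8 features with GPR for RR, and RReliefF top-11 with GPR for SpO2.

A thin command-line wrapper ships in `inst/cli/ppgvitals`
(`simulate`, `segment`, `preprocess`, `extract`, `select`, `evaluate`,
`reproduce-synthetic` subcommands).

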