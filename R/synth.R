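# Synthetic PPG generator: two-Gaussian pulse trains with respiratory
# amplitude/frequency/baseline modulation, an SpO2-linked morphology
# surrogate, broadband noise, and sporadic low-frequency motion artifacts.
# Ground-truth landmark times are emitted for oracle-style testing.

#' Synthetic segment configuration
#'
#' The defaults emulate the study conditions the pipeline targets: 32 s
#' windows at 125 Hz, respiration rate in 5-25 breaths/min, SpO2 in 84-100%.
#' Beat-level morphology is a two-Gaussian (systolic + diastolic) template;
#' widths and offsets are expressed at a reference 1 s beat period and scale
#' with each beat's actual period so morphology stays physiological across
#' heart rates. The SpO2 link is a declared test-scaffold surrogate (a
#' single-channel PPG cannot encode true ratio-of-ratios oximetry): the
#' diastolic-to-systolic amplitude ratio is `0.30 + 0.02 * (100 - spo2)` and
#' the systolic width scales by `1 + 0.01 * (100 - spo2)`.
#'
#' @param fs sampling frequency, Hz.
#' @param duration_s segment length, s.
#' @param hr_bpm mean heart rate, beats/min.
#' @param rr_bpm respiration rate, breaths/min (study range 5-25).
#' @param spo2_pct oxygen saturation, percent (study range 84-100).
#' @param am,fm,bw respiratory amplitude-, frequency- and baseline-modulation
#'   depths, fractions in `[0, 1)`.
#' @param sigma_sys,sigma_dia Gaussian widths (s at 1 s beat period).
#' @param peak_frac,dia_frac systolic-peak and diastolic-bump centers as
#'   fractions of the beat period.
#' @param noise_snr_db additive white-noise SNR relative to the clean signal
#'   (`Inf` = noise-free).
#' @param artifact_rate_per_min,artifact_amplitude,artifact_width_s sporadic
#'   low-frequency motion-artifact bumps (Poisson-placed Gaussians).
#' @param seed integer seed; the segment is a deterministic function of the
#'   full configuration.
#' @return a list of class `synth_config`.
#' @export
synth_config <- function(fs = 125, duration_s = 32, hr_bpm = 75, rr_bpm = 15,
                         spo2_pct = 97, am = 0.10, fm = 0.03, bw = 0.15,
                         sigma_sys = 0.07, sigma_dia = 0.10,
                         peak_frac = 0.30, dia_frac = 0.60,
                         noise_snr_db = 25, artifact_rate_per_min = 0.3,
                         artifact_amplitude = 1.5, artifact_width_s = 3,
                         seed = 1) {
  if (rr_bpm < 1 || rr_bpm > 60) stop2("rr_bpm %g out of range", rr_bpm)
  if (spo2_pct < 50 || spo2_pct > 100) stop2("spo2_pct %g out of range", spo2_pct)
  if (any(c(am, fm, bw) < 0) || any(c(am, fm, bw) >= 1))
    stop2("modulation depths must lie in [0, 1)")
  structure(as.list(environment()), class = "synth_config")
}

#' Generate one labeled synthetic PPG segment with ground truth
#'
#' Beat times follow the instantaneous heart rate
#' `hr * (1 + fm * sin(2 pi f_R t))` with `f_R = rr/60`; beat k's amplitude is
#' `1 + am * sin(2 pi f_R t_k)`; a baseline `bw * sin(2 pi f_R t)` is added.
#' Each beat is rendered on its own period, so the programmed onset of beat k
#' is exactly `t_k` and the programmed systolic peak is the sample-grid
#' argmax of the clean beat. White Gaussian noise at `noise_snr_db` and
#' Poisson-placed low-frequency artifact bumps are added last.
#'
#' @param config a [synth_config()].
#' @return list with `segment` (a labeled [ppg_segment()]) and `truth`
#'   (class `synth_truth`): `onset_times`, `peak_times`, `peak_idx` (1-based
#'   sample indices), `n_beats`, `rr_bpm`, `spo2_pct`, `clean` (pre-noise,
#'   pre-artifact samples), `rho` (diastolic amplitude ratio used).
#' @export
generate_segment <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  cf <- config
  set.seed(cf$seed)
  n <- round(cf$duration_s * cf$fs)
  t <- (0:(n - 1)) / cf$fs
  f_r <- cf$rr_bpm / 60
  f_hr <- cf$hr_bpm / 60

  # beat times from the integrated instantaneous rate (phase crossings of
  # integers), extended one beat beyond each edge for complete rendering
  tg <- seq(-2 / f_hr, cf$duration_s + 2 / f_hr, by = 1 / (4 * cf$fs))
  phase <- f_hr * (tg + if (cf$fm > 0 && f_r > 0)
    cf$fm * (1 - cos(2 * pi * f_r * tg)) / (2 * pi * f_r) else 0)
  ks <- seq(ceiling(min(phase)), floor(max(phase)))
  beat_times <- approx(phase, tg, xout = ks)$y
  beat_times <- beat_times[is.finite(beat_times)]

  rho <- 0.30 + 0.02 * (100 - cf$spo2_pct)
  s_sys <- cf$sigma_sys * (1 + 0.01 * (100 - cf$spo2_pct))
  s_dia <- cf$sigma_dia

  clean <- numeric(n)
  onset_times <- c(); peak_idx <- c()
  nb <- length(beat_times)
  for (k in seq_len(nb - 1)) {
    t0 <- beat_times[k]; Tk <- beat_times[k + 1] - t0
    sel <- which(t >= t0 & t < t0 + Tk)
    if (length(sel) == 0) next
    tau <- t[sel] - t0
    A <- 1 + cf$am * sin(2 * pi * f_r * t0)
    pulse <- A * (exp(-(tau - cf$peak_frac * Tk)^2 / (2 * (s_sys * Tk)^2)) +
                  rho * exp(-(tau - cf$dia_frac * Tk)^2 / (2 * (s_dia * Tk)^2)))
    clean[sel] <- clean[sel] + pulse
    if (t0 >= 0 && t0 < cf$duration_s) {
      onset_times <- c(onset_times, t0)
      peak_idx <- c(peak_idx, sel[which.max(pulse)])
    }
  }
  clean <- clean + cf$bw * sin(2 * pi * f_r * t)

  x <- clean
  if (is.finite(cf$noise_snr_db)) {
    npow <- mean((clean - mean(clean))^2) / 10^(cf$noise_snr_db / 10)
    x <- x + rnorm(n, sd = sqrt(npow))
  }
  n_art <- rpois(1, cf$artifact_rate_per_min * cf$duration_s / 60)
  if (n_art > 0) {
    for (j in seq_len(n_art)) {
      ctr <- runif(1, 0, cf$duration_s)
      amp <- cf$artifact_amplitude * sample(c(-1, 1), 1)
      x <- x + amp * exp(-(t - ctr)^2 / (2 * (cf$artifact_width_s / 2)^2))
    }
  }

  seg <- ppg_segment(x, cf$fs, start_time = 0, rr_label = cf$rr_bpm,
                     spo2_label = cf$spo2_pct,
                     record_id = sprintf("synth_seed%d", cf$seed))
  truth <- structure(list(onset_times = onset_times,
                          peak_times = t[peak_idx], peak_idx = peak_idx,
                          n_beats = length(onset_times),
                          rr_bpm = cf$rr_bpm, spo2_pct = cf$spo2_pct,
                          clean = clean, rho = rho, config = cf),
                     class = "synth_truth")
  list(segment = seg, truth = truth)
}

#' Generate a labeled synthetic corpus
#'
#' Draws per-segment respiration rate, SpO2 and heart rate uniformly from the
#' configured ranges (defaults: the study population's 5-25 breaths/min and
#' 84-100%), with per-segment seeds derived reproducibly from `seed`.
#'
#' @param n number of segments.
#' @param seed master seed.
#' @param rr_range,spo2_range,hr_range uniform sampling ranges.
#' @param ... further arguments forwarded to [synth_config()] (e.g.
#'   `noise_snr_db = Inf` for a noise-free corpus).
#' @return list with `segments` (a `segment_set`) and `truths` (list of
#'   `synth_truth`).
#' @export
generate_corpus <- function(n, seed = 1, rr_range = c(5, 25),
                            spo2_range = c(84, 100), hr_range = c(55, 95),
                            ...) {
  stopifnot(n >= 1)
  set.seed(seed)
  rr <- runif(n, rr_range[1], rr_range[2])
  spo2 <- runif(n, spo2_range[1], spo2_range[2])
  hr <- runif(n, hr_range[1], hr_range[2])
  seeds <- sample.int(.Machine$integer.max - 1, n)
  out <- lapply(seq_len(n), function(i) {
    generate_segment(synth_config(hr_bpm = hr[i], rr_bpm = rr[i],
                                  spo2_pct = spo2[i], seed = seeds[i], ...))
  })
  segs <- structure(list(segments = lapply(out, `[[`, "segment"),
                         provenance = list(record_ids = "synthetic",
                                           window_s = list(...)$duration_s %||% 32,
                                           overlap = 0, seed = seed, n = n)),
                    class = "segment_set")
  list(segments = segs, truths = lapply(out, `[[`, "truth"))
}
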