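# Pulse delineation: onsets, systolic peaks, dicrotic notch, diastolic peak,
# and second-derivative a-e waves, plus the per-beat interval table.

# peak prominence: height above the higher of the two bounding minima, where
# each bound is the minimum between the peak and the nearest higher sample
.prominences <- function(x, peaks) {
  n <- length(x)
  vapply(peaks, function(p) {
    h <- x[p]
    l <- p; lmin <- h
    while (l > 1 && x[l] <= h) { l <- l - 1; lmin <- min(lmin, x[l]) }
    r <- p; rmin <- h
    while (r < n && x[r] <= h) { r <- r + 1; rmin <- min(rmin, x[r]) }
    if (x[l] > h && x[r] > h) h - max(lmin, rmin)
    else if (x[l] > h) h - lmin
    else if (x[r] > h) h - rmin
    else h - max(lmin, rmin)
  }, 0)
}

.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

# smoothed derivative helpers (Savitzky-Golay, window 11, order 3)
.smooth_deriv <- function(x, fs, sg_n = 11, sg_p = 3) {
  d1 <- c(0, diff(x)) * fs
  d2 <- c(0, 0, diff(x, differences = 2)) * fs^2
  if (length(x) > sg_n) {
    d1 <- signal::sgolayfilt(d1, p = sg_p, n = sg_n)
    d2 <- signal::sgolayfilt(d2, p = sg_p, n = sg_n)
  }
  list(d1 = d1, d2 = d2)
}

#' Delineate the pulses in a preprocessed PPG segment
#'
#' Systolic peaks are local maxima with adaptive prominence (at least
#' `prominence_frac` of the segment's robust 5-95% amplitude range) separated
#' by at least `0.4 / f_HR` seconds, where `f_HR` is the spectral peak in the
#' cardiac band 0.7-3.5 Hz. Onsets are the minima between consecutive peaks.
#' The dicrotic notch and diastolic peak are located from zero-crossings of
#' the Savitzky-Golay-smoothed first derivative inside the diastolic interval,
#' falling back to the minimum of the smoothed second derivative when the
#' waveform carries only a shoulder. The a-e waves are the first five
#' alternating extrema of the smoothed second derivative after the onset.
#' Beats violating the ordering invariants (onset < systolic peak < next
#' onset, positive amplitude) are discarded and counted.
#'
#' @param segment a [ppg_segment()] or numeric vector.
#' @param fs sampling frequency (taken from segment if omitted).
#' @param prominence_frac minimum peak prominence as a fraction of the robust
#'   amplitude range (default 0.3).
#' @param sg_n,sg_p Savitzky-Golay window length and polynomial order for the
#'   derivative smoothing (defaults 11 and 3).
#' @return object of class `pulse_fiducials`: `beats` (data frame, one row per
#'   valid beat), `fs`, `f_hr_est`, `n_discarded`, `analyzable`. Index columns
#'   are 1-based sample indices into the segment; `t1` (onset to systolic
#'   peak, s), `tpi` (onset to next onset, s; `NA` for the final beat), and
#'   amplitudes are measured relative to the onset baseline.
#' @export
detect_pulses <- function(segment, fs = NULL, prominence_frac = 0.3,
                          sg_n = 11, sg_p = 3) {
  is_seg <- inherits(segment, "ppg_segment")
  x <- as_segment_samples(segment)
  fs <- fs %||% (if (is_seg) segment$fs else NULL)
  if (is.null(fs)) stop2("fs must be supplied for a bare numeric vector")
  unanalyzable <- function(reason) {
    structure(list(beats = NULL, fs = fs, f_hr_est = NA_real_,
                   n_discarded = 0L, analyzable = FALSE, reason = reason),
              class = "pulse_fiducials")
  }
  if (length(x) < 2 * fs || sd(x) == 0)
    return(unanalyzable("constant or too-short segment"))

  pg <- periodogram_hann(x, fs)
  band <- pg$freq >= 0.7 & pg$freq <= 3.5
  if (!any(band) || all(pg$power[band] == 0))
    return(unanalyzable("no cardiac-band spectral content"))
  f_hr <- pg$freq[band][which.max(pg$power[band])]
  min_dist <- max(1L, round(0.4 / f_hr * fs))

  rng <- diff(quantile(x, c(0.05, 0.95), names = FALSE))
  if (rng <= 0) return(unanalyzable("flat amplitude distribution"))
  cand <- .local_maxima(x)
  if (length(cand) == 0) return(unanalyzable("no local maxima"))
  prom <- .prominences(x, cand)
  cand <- cand[prom >= prominence_frac * rng]
  if (length(cand) == 0) return(unanalyzable("no prominent peaks"))
  # enforce minimum distance, keeping taller peaks first
  keep <- logical(length(cand))
  for (i in order(x[cand], decreasing = TRUE)) {
    if (!any(keep & abs(cand - cand[i]) < min_dist)) keep[i] <- TRUE
  }
  peaks <- sort(cand[keep])
  if (length(peaks) < 3) return(unanalyzable("fewer than 3 beats detected"))

  # onsets: minimum between consecutive peaks; first onset looks back one
  # expected period before the first peak
  onsets <- integer(length(peaks))
  lo <- max(1L, peaks[1] - round(fs / f_hr))
  onsets[1] <- lo + which.min(x[lo:(peaks[1] - 1)]) - 1L
  for (i in 2:length(peaks)) {
    span <- (peaks[i - 1] + 1L):(peaks[i] - 1L)
    onsets[i] <- span[which.min(x[span])]
  }

  dv <- .smooth_deriv(x, fs, sg_n, sg_p)
  m <- length(peaks)
  rows <- vector("list", m)
  discarded <- 0L
  for (i in seq_len(m)) {
    on <- onsets[i]; pk <- peaks[i]
    nxt <- if (i < m) onsets[i + 1] else NA_integer_
    if (!(on < pk) || (!is.na(nxt) && !(pk < nxt))) { discarded <- discarded + 1L; next }
    sys_amp <- x[pk] - x[on]
    if (!(sys_amp > 0)) { discarded <- discarded + 1L; next }

    notch <- dia <- NA_integer_
    if (!is.na(nxt) && nxt - pk > 3) {
      iv <- (pk + 1L):(nxt - 1L)
      d1iv <- dv$d1[iv]
      sgn <- sign(d1iv)
      cross_up <- which(sgn[-length(sgn)] <= 0 & sgn[-1] > 0)    # local min of x
      cross_dn <- which(sgn[-length(sgn)] >= 0 & sgn[-1] < 0)    # local max of x
      if (length(cross_up) > 0) {
        notch <- iv[cross_up[1]]
        after <- cross_dn[cross_dn > cross_up[1]]
        if (length(after) > 0) dia <- iv[after[1]]
      } else {
        # shoulder-only diastole: fall back to the minimum of the smoothed
        # second derivative in the diastolic interval
        notch <- iv[which.min(dv$d2[iv])]
        rest <- iv[iv > notch]
        if (length(rest) > 2) {
          lm2 <- rest[which.max(dv$d2[rest])]
          dia <- if (lm2 > notch + 1) lm2 else NA_integer_
        }
      }
      if (!is.na(notch) && (notch <= pk || notch >= nxt)) notch <- NA_integer_
      if (!is.na(dia) && (dia <= pk || dia >= nxt)) dia <- NA_integer_
    }

    # a-e waves: first five alternating extrema of d2 at/after the onset,
    # starting with a maximum
    upper <- if (!is.na(nxt)) nxt else min(length(x), pk + round(fs / f_hr))
    abcde <- rep(NA_integer_, 5)
    if (upper - on > 5) {
      iv2 <- on:upper
      d2iv <- dv$d2[iv2]
      n2 <- length(d2iv)
      lmax <- .local_maxima(d2iv)
      lmin <- .local_maxima(-d2iv)
      pos <- 0L
      want_max <- TRUE
      for (w in 1:5) {
        pool <- if (want_max) lmax[lmax > pos] else lmin[lmin > pos]
        if (length(pool) == 0) break
        pos <- pool[1]
        abcde[w] <- iv2[pos]
        want_max <- !want_max
      }
    }
    amp_at <- function(idx) if (is.na(idx)) NA_real_ else x[idx] - x[on]
    rows[[i]] <- data.frame(
      beat = i, onset_idx = on, sys_peak_idx = pk, notch_idx = notch,
      dia_peak_idx = dia,
      a_idx = abcde[1], b_idx = abcde[2], c_idx = abcde[3],
      d_idx = abcde[4], e_idx = abcde[5],
      a_amp = if (is.na(abcde[1])) NA_real_ else dv$d2[abcde[1]],
      b_amp = if (is.na(abcde[2])) NA_real_ else dv$d2[abcde[2]],
      c_amp = if (is.na(abcde[3])) NA_real_ else dv$d2[abcde[3]],
      d_amp = if (is.na(abcde[4])) NA_real_ else dv$d2[abcde[4]],
      e_amp = if (is.na(abcde[5])) NA_real_ else dv$d2[abcde[5]],
      t1 = (pk - on) / fs,
      tpi = if (is.na(nxt)) NA_real_ else (nxt - on) / fs,
      sys_amp = sys_amp, notch_amp = amp_at(notch), dia_amp = amp_at(dia))
  }
  beats <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(beats) || nrow(beats) < 3)
    return(unanalyzable("fewer than 3 valid beats"))
  beats$beat <- seq_len(nrow(beats))
  structure(list(beats = beats, fs = fs, f_hr_est = f_hr,
                 n_discarded = discarded, analyzable = TRUE, reason = NULL,
                 samples = x),
            class = "pulse_fiducials")
}

#' @export
print.pulse_fiducials <- function(x, ...) {
  if (!x$analyzable) {
    cat(sprintf("<pulse_fiducials>: unanalyzable (%s)\n", x$reason))
  } else {
    cat(sprintf("<pulse_fiducials>: %d beats (f_HR ~ %.2f Hz, %d discarded)\n",
                nrow(x$beats), x$f_hr_est, x$n_discarded))
  }
  invisible(x)
}

# interpolated crossing time of `level` between samples, searching from the
# peak outwards; returns NA if never crossed
.cross_left <- function(x, from, to, level, fs) {
  # walk left from `to` (peak) down to `from` (onset)
  for (i in to:(from + 1)) {
    if (x[i - 1] <= level && x[i] >= level) {
      frac <- if (x[i] == x[i - 1]) 0 else (level - x[i - 1]) / (x[i] - x[i - 1])
      return((i - 1 + frac - 1) / fs)
    }
  }
  NA_real_
}

.cross_right <- function(x, from, to, level, fs) {
  if (to <= from) return(NA_real_)
  for (i in from:(to - 1)) {
    if (x[i] >= level && x[i + 1] <= level) {
      frac <- if (x[i + 1] == x[i]) 0 else (x[i] - level) / (x[i] - x[i + 1])
      return((i + frac - 1) / fs)
    }
  }
  NA_real_
}

#' Per-beat interval and width table
#'
#' Expands the fiducials into the timing quantities the feature catalog uses:
#' `t1`, `tpi`, `t1/tpi`, rise and fall times, and pulse widths at 25/50/75%
#' of the systolic amplitude (linear interpolation of the threshold crossings
#' on each side of the systolic peak; a width is `NA` when its level is never
#' crossed on one side, e.g. for clipped beats).
#'
#' @param fid a `pulse_fiducials` object from [detect_pulses()].
#' @return data frame, one row per beat, with columns `t1`, `tpi`,
#'   `t1_tpi`, `rise_time`, `fall_time`, `width25`, `width50`, `width75`,
#'   `sys_amp`, `dia_amp`, `notch_amp`, `dia_sys_ratio`, `notch_time_ratio`
#'   plus the a-e amplitudes and their ratios.
#' @export
beat_intervals <- function(fid) {
  stopifnot(inherits(fid, "pulse_fiducials"))
  if (!fid$analyzable) stop2("segment is unanalyzable: %s", fid$reason)
  b <- fid$beats
  x <- fid$samples
  fs <- fid$fs
  m <- nrow(b)
  widths <- matrix(NA_real_, m, 3)
  for (i in seq_len(m)) {
    on <- b$onset_idx[i]; pk <- b$sys_peak_idx[i]
    nxt <- if (i < m) b$onset_idx[i + 1] else NA_integer_
    # use the recorded tpi to find the right-hand search bound for the last beat
    rbound <- if (!is.na(nxt)) nxt else min(length(x), pk + (pk - on) * 4L)
    for (w in 1:3) {
      level <- x[on] + c(0.25, 0.5, 0.75)[w] * b$sys_amp[i]
      tl <- .cross_left(x, on, pk, level, fs)
      tr <- .cross_right(x, pk, rbound, level, fs)
      if (!is.na(tl) && !is.na(tr)) widths[i, w] <- tr - tl
    }
  }
  fall <- ifelse(is.na(b$tpi), NA_real_, b$tpi - b$t1)
  data.frame(
    beat = b$beat,
    t1 = b$t1, tpi = b$tpi, t1_tpi_ratio = b$t1 / b$tpi,
    rise_time = b$t1, fall_time = fall,
    width25 = widths[, 1], width50 = widths[, 2], width75 = widths[, 3],
    sys_amp = b$sys_amp, dia_amp = b$dia_amp, notch_amp = b$notch_amp,
    dia_sys_ratio = b$dia_amp / b$sys_amp,
    notch_time_ratio = ((b$notch_idx - b$onset_idx) / fid$fs) / b$tpi,
    a_amp = b$a_amp, b_amp = b$b_amp, c_amp = b$c_amp, d_amp = b$d_amp,
    e_amp = b$e_amp,
    b_a = b$b_amp / b$a_amp, c_a = b$c_amp / b$a_amp,
    d_a = b$d_amp / b$a_amp, e_a = b$e_amp / b$a_amp,
    aging_index = (b$b_amp - b$c_amp - b$d_amp - b$e_amp) / b$a_amp,
    mod_aging_index = (b$b_amp - b$e_amp) / b$a_amp)
}
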