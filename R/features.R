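# The fixed 107-entry feature catalog and its extractor.
#
# Group layout (107 total, contract-enforced):
#   time       39 = 13 beat quantities x {mean, sd, var}
#   derivative 22 = 11 second-derivative quantities x {mean, sd}
#   frequency  15   spectral descriptors of the Hann periodogram
#   statistical 31 = 13 moments of the signal + 9 each of its first and
#                    second differences
#
# Moment conventions (the catalog states them because they are not universal):
# skewness and kurtosis are population forms (kurtosis non-excess: a normal
# signal scores 3, a pure sine 1.5); SD/variance in the statistical group are
# population (divide by n); beat statistics across beats use the sample SD.

.BEAT_QUANTITIES <- c("sys_amp", "dia_amp", "notch_amp", "t1", "tpi", "t1_tpi_ratio",
                      "rise_time", "fall_time", "width25", "width50", "width75",
                      "dia_sys_ratio", "notch_time_ratio")
.DERIV_QUANTITIES <- c("a_amp", "b_amp", "c_amp", "d_amp", "e_amp",
                       "b_a", "c_a", "d_a", "e_a", "aging_index",
                       "mod_aging_index")
.FREQ_FEATURES <- c("max_frequency", "max_frequency_mag",
                    "resp_peak_freq", "cardiac_peak_freq",
                    "peak1_freq", "peak2_freq", "peak3_freq",
                    "peak1_mag", "peak2_mag", "peak3_mag",
                    "resp_band_ratio", "cardiac_band_ratio",
                    "harmonic_band_ratio",
                    "spectral_centroid", "spectral_entropy")
.STAT_SIGNAL <- c("mean", "median", "sd", "var", "skewness", "kurtosis",
                  "rms", "iqr", "mad", "shannon_entropy", "zcr",
                  "hjorth_mobility", "hjorth_complexity")
.STAT_DERIV <- c("mean", "sd", "var", "skewness", "kurtosis", "rms",
                 "iqr", "mad", "zcr")

# frequency bands (Hz): respiratory covers 3-36 breaths/min, cardiac
# 42-210 beats/min, harmonic the first overtones of the cardiac band
.RESP_BAND <- c(0.05, 0.6)
.CARDIAC_BAND <- c(0.7, 3.5)
.HARMONIC_BAND <- c(3.5, 10)

#' The fixed feature catalog
#'
#' Deterministic ordered table of the 107 features the extractor computes.
#' The count is a hard contract: [extract_features()] always returns exactly
#' these names in this order.
#'
#' @return data frame with columns `name`, `group`, `units`, `definition`
#'   (107 rows).
#' @export
feature_catalog <- function() {
  rows <- list()
  unit_of <- function(q) {
    if (q %in% c("t1", "tpi", "rise_time", "fall_time",
                 "width25", "width50", "width75")) "s"
    else if (q %in% c("t1_tpi_ratio", "dia_sys_ratio", "notch_time_ratio")) "ratio"
    else "a.u."
  }
  for (q in .BEAT_QUANTITIES) for (s in c("mean", "sd", "var")) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0(q, "_", s), group = "time", units = unit_of(q),
      definition = sprintf("%s of per-beat %s", s, q))
  }
  for (q in .DERIV_QUANTITIES) for (s in c("mean", "sd")) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0(q, "_", s), group = "derivative",
      units = if (grepl("_a$|index", q)) "ratio" else "a.u./s^2",
      definition = sprintf("%s of per-beat second-derivative %s", s, q))
  }
  freq_defs <- c(
    max_frequency = "frequency of the maximum periodogram ordinate",
    max_frequency_mag = "periodogram ordinate at max_frequency",
    resp_peak_freq = "interpolated spectral peak in 0.05-0.6 Hz",
    cardiac_peak_freq = "interpolated spectral peak in 0.7-3.5 Hz",
    peak1_freq = "frequency of the largest spectral peak",
    peak2_freq = "frequency of the 2nd largest spectral peak",
    peak3_freq = "frequency of the 3rd largest spectral peak",
    peak1_mag = "magnitude of the largest spectral peak",
    peak2_mag = "magnitude of the 2nd largest spectral peak",
    peak3_mag = "magnitude of the 3rd largest spectral peak",
    resp_band_ratio = "power fraction in 0.05-0.6 Hz",
    cardiac_band_ratio = "power fraction in 0.7-3.5 Hz",
    harmonic_band_ratio = "power fraction in 3.5-10 Hz",
    spectral_centroid = "power-weighted mean frequency",
    spectral_entropy = "normalized Shannon entropy of the power spectrum")
  for (q in .FREQ_FEATURES) {
    rows[[length(rows) + 1]] <- data.frame(
      name = q, group = "frequency",
      units = if (grepl("freq|centroid", q)) "Hz"
              else if (grepl("ratio|entropy", q)) "ratio" else "a.u.",
      definition = unname(freq_defs[q]))
  }
  for (q in .STAT_SIGNAL) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0("sig_", q), group = "statistical",
      units = if (q %in% c("zcr")) "1/s" else "a.u.",
      definition = sprintf("%s of the segment samples", q))
  }
  for (d in c("d1", "d2")) for (q in .STAT_DERIV) {
    rows[[length(rows) + 1]] <- data.frame(
      name = paste0(d, "_", q), group = "statistical",
      units = if (q %in% c("zcr")) "1/s" else "a.u.",
      definition = sprintf("%s of the %s difference of the segment",
                           q, if (d == "d1") "first" else "second"))
  }
  out <- do.call(rbind, rows)
  stopifnot(nrow(out) == 107, !anyDuplicated(out$name))
  out
}

# population moments
.pskew <- function(x) {
  m <- mean(x); m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  if (m2 == 0) return(NA_real_)
  m3 / m2^1.5
}
.pkurt <- function(x) {
  m <- mean(x); m2 <- mean((x - m)^2); m4 <- mean((x - m)^4)
  if (m2 == 0) return(NA_real_)
  m4 / m2^2
}
.psd <- function(x) sqrt(mean((x - mean(x))^2))
.zcr <- function(x, fs) {
  xc <- x - mean(x)
  s <- sign(xc)
  s <- s[s != 0]
  if (length(s) < 2) return(0)
  sum(s[-1] != s[-length(s)]) / (length(x) / fs)
}
.shannon_entropy <- function(x, bins = 16) {
  if (diff(range(x)) == 0) return(0)
  h <- tabulate(cut(x, breaks = seq(min(x), max(x), length.out = bins + 1),
                    include.lowest = TRUE, labels = FALSE), nbins = bins)
  p <- h / sum(h)
  p <- p[p > 0]
  -sum(p * log2(p))
}
.hjorth <- function(x) {
  v0 <- mean((x - mean(x))^2)
  d1 <- diff(x); v1 <- mean((d1 - mean(d1))^2)
  d2 <- diff(d1); v2 <- mean((d2 - mean(d2))^2)
  mob <- if (v0 > 0) sqrt(v1 / v0) else NA_real_
  cmp <- if (v1 > 0 && !is.na(mob) && mob > 0) sqrt(v2 / v1) / mob else NA_real_
  c(mobility = mob, complexity = cmp)
}

.stat_block <- function(x, fs, full = TRUE) {
  out <- c(mean = mean(x), median = median(x), sd = .psd(x),
           var = mean((x - mean(x))^2), skewness = .pskew(x),
           kurtosis = .pkurt(x), rms = sqrt(mean(x^2)),
           iqr = IQR(x), mad = mad(x, constant = 1))
  if (full) {
    hj <- .hjorth(x)
    out <- c(out, shannon_entropy = .shannon_entropy(x), zcr = .zcr(x, fs),
             hjorth_mobility = unname(hj["mobility"]),
             hjorth_complexity = unname(hj["complexity"]))
    out[.STAT_SIGNAL]
  } else {
    c(out, zcr = .zcr(x, fs))[.STAT_DERIV]
  }
}

.freq_block <- function(x, fs) {
  pg <- periodogram_hann(x, fs)
  f <- pg$freq; p <- pg$power
  out <- setNames(rep(NA_real_, length(.FREQ_FEATURES)), .FREQ_FEATURES)
  tot <- sum(p)
  if (tot <= 0 || !is.finite(tot)) return(out)
  imax <- which.max(p)
  out["max_frequency"] <- f[imax]
  out["max_frequency_mag"] <- p[imax]
  band_peak <- function(lo, hi) {
    sel <- which(f >= lo & f <= hi)
    if (length(sel) == 0) return(NA_real_)
    i <- sel[which.max(p[sel])]
    .interp_peak(f, p, i)
  }
  out["resp_peak_freq"] <- band_peak(.RESP_BAND[1], .RESP_BAND[2])
  out["cardiac_peak_freq"] <- band_peak(.CARDIAC_BAND[1], .CARDIAC_BAND[2])
  lm <- .local_maxima(p)
  if (length(lm) > 0) {
    lm <- lm[order(p[lm], decreasing = TRUE)]
    for (k in 1:3) {
      if (k <= length(lm)) {
        out[paste0("peak", k, "_freq")] <- f[lm[k]]
        out[paste0("peak", k, "_mag")] <- p[lm[k]]
      }
    }
  }
  bandpow <- function(lo, hi) sum(p[f >= lo & f <= hi])
  out["resp_band_ratio"] <- bandpow(.RESP_BAND[1], .RESP_BAND[2]) / tot
  out["cardiac_band_ratio"] <- bandpow(.CARDIAC_BAND[1], .CARDIAC_BAND[2]) / tot
  out["harmonic_band_ratio"] <- bandpow(.HARMONIC_BAND[1], .HARMONIC_BAND[2]) / tot
  out["spectral_centroid"] <- sum(f * p) / tot
  pn <- p / tot
  pn <- pn[pn > 0]
  out["spectral_entropy"] <- -sum(pn * log2(pn)) / log2(length(p))
  out
}

#' Extract the 107-feature vector from a segment
#'
#' Beat-statistic features use only beats passing the ordering invariants;
#' per-quantity `NA`s (e.g. undetectable dicrotic notches) are excluded from
#' the per-segment means. Frequency features use a Hann-windowed periodogram
#' of the mean-removed segment. Unanalyzable segments yield `NA` for all
#' fiducial-derived features while spectral and statistical features are still
#' computed.
#'
#' @param segment a [ppg_segment()] or numeric vector.
#' @param fiducials optional precomputed [detect_pulses()] result; computed
#'   here when missing.
#' @param fs sampling frequency (taken from segment if omitted).
#' @return named numeric vector of length 107 (names = `feature_catalog()$name`);
#'   `NA` marks missing values.
#' @export
extract_features <- function(segment, fiducials = NULL, fs = NULL) {
  x <- as_segment_samples(segment)
  fs <- fs %||% (if (inherits(segment, "ppg_segment")) segment$fs else NULL)
  if (is.null(fs)) stop2("fs must be supplied for a bare numeric vector")
  if (length(x) == 0) stop2("empty segment")
  catalog <- feature_catalog()
  out <- setNames(rep(NA_real_, 107), catalog$name)

  if (is.null(fiducials)) fiducials <- detect_pulses(x, fs)
  if (fiducials$analyzable) {
    bi <- beat_intervals(fiducials)
    stat3 <- function(v) {
      v <- v[is.finite(v)]
      c(mean = if (length(v) >= 1) mean(v) else NA_real_,
        sd = if (length(v) >= 2) sd(v) else NA_real_,
        var = if (length(v) >= 2) var(v) else NA_real_)
    }
    for (q in .BEAT_QUANTITIES) {
      s <- stat3(bi[[q]])
      out[paste0(q, c("_mean", "_sd", "_var"))] <- s
    }
    for (q in .DERIV_QUANTITIES) {
      s <- stat3(bi[[q]])
      out[paste0(q, c("_mean", "_sd"))] <- s[c("mean", "sd")]
    }
  }

  out[.FREQ_FEATURES] <- .freq_block(x, fs)
  out[paste0("sig_", .STAT_SIGNAL)] <- .stat_block(x, fs, full = TRUE)
  out[paste0("d1_", .STAT_DERIV)] <- .stat_block(diff(x) * fs, fs, full = FALSE)
  out[paste0("d2_", .STAT_DERIV)] <- .stat_block(diff(x, differences = 2) * fs^2,
                                                 fs, full = FALSE)
  stopifnot(length(out) == 107)
  out
}

#' Build a feature matrix from a segment set
#'
#' Runs (or accepts precomputed) feature vectors for every segment and stacks
#' them with the RR/SpO2 labels. Columns with more than 50% missing values
#' across rows are flagged in the `high_missing` attribute.
#'
#' @param segments a `segment_set` (preprocessed).
#' @param vectors optional list of precomputed feature vectors (one per
#'   segment, each length 107).
#' @return object of class `feature_matrix`: `X` (n x 107 matrix), `labels`
#'   (data frame with `rr`, `spo2`), `provenance`, `high_missing` (character
#'   vector of flagged column names).
#' @export
build_matrix <- function(segments, vectors = NULL) {
  stopifnot(inherits(segments, "segment_set"))
  n <- length(segments$segments)
  if (is.null(vectors)) {
    vectors <- lapply(segments$segments, extract_features)
  }
  if (length(vectors) != n) stop2("one feature vector per segment required")
  X <- do.call(rbind, vectors)
  stopifnot(ncol(X) == 107)
  rownames(X) <- NULL
  labels <- data.frame(
    rr = vapply(segments$segments, function(s) s$rr_label %||% NA_real_, 0),
    spo2 = vapply(segments$segments, function(s) s$spo2_label %||% NA_real_, 0))
  miss <- colMeans(is.na(X))
  structure(list(X = X, labels = labels,
                 provenance = segments$provenance,
                 high_missing = colnames(X)[miss > 0.5]),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf("<feature_matrix>: %d segments x %d features (%d high-missing columns)\n",
              nrow(x$X), ncol(x$X), length(x$high_missing)))
  invisible(x)
}

# train-only preprocessing parameter fits (leakage-safe by construction) -----

#' Fit median imputation parameters on training rows
#' @param X numeric matrix.
#' @param rows training row indices (default all).
#' @return list of class `imputer` with per-column medians.
#' @export
fit_imputer <- function(X, rows = seq_len(nrow(X))) {
  med <- apply(X[rows, , drop = FALSE], 2, median, na.rm = TRUE)
  med[!is.finite(med)] <- 0
  structure(list(medians = med), class = "imputer")
}

#' Apply a fitted imputer
#' @param imp an `imputer`.
#' @param X numeric matrix.
#' @return X with `NA`s replaced by the training medians.
#' @export
apply_imputer <- function(imp, X) {
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- imp$medians[j]
  }
  X
}

#' Fit z-score standardization parameters on training rows
#' @param X numeric matrix (imputed).
#' @param rows training row indices (default all).
#' @return list of class `standardizer` with `center` and `scale` (columns
#'   with zero variance get scale 1).
#' @export
fit_standardizer <- function(X, rows = seq_len(nrow(X))) {
  Xt <- X[rows, , drop = FALSE]
  ctr <- colMeans(Xt)
  scl <- apply(Xt, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  structure(list(center = ctr, scale = scl), class = "standardizer")
}

#' Apply a fitted standardizer
#' @param std a `standardizer`.
#' @param X numeric matrix.
#' @return standardized matrix.
#' @export
apply_standardizer <- function(std, X) {
  sweep(sweep(X, 2, std$center, "-"), 2, std$scale, "/")
}

#' Write a feature matrix to CSV
#' @param fm a `feature_matrix`.
#' @param path output CSV path (feature columns + `rr_label`, `spo2_label`).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  tab <- as.data.frame(fm$X)
  tab$rr_label <- fm$labels$rr
  tab$spo2_label <- fm$labels$spo2
  write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature matrix written by [write_feature_matrix()]
#' @param path CSV path.
#' @return a `feature_matrix`.
#' @export
read_feature_matrix <- function(path) {
  tab <- read.csv(path, check.names = FALSE)
  lab <- data.frame(rr = tab$rr_label, spo2 = tab$spo2_label)
  X <- as.matrix(tab[setdiff(names(tab), c("rr_label", "spo2_label"))])
  miss <- colMeans(is.na(X))
  structure(list(X = X, labels = lab, provenance = list(source = path),
                 high_missing = colnames(X)[miss > 0.5]),
            class = "feature_matrix")
}
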