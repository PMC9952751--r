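# Zero-phase Butterworth low-pass filtering and VMD-based motion-artifact
# suppression.

#' Butterworth low-pass filter specification
#'
#' `order` is the per-pass design order; forward-backward application squares
#' the magnitude response, doubling the stop-band attenuation in dB.
#'
#' @param order filter order per pass (default 6).
#' @param cutoff_hz -3 dB cutoff per pass in Hz (default 25).
#' @return an object of class `filter_spec`.
#' @export
filter_spec <- function(order = 6, cutoff_hz = 25) {
  stopifnot(order >= 1, cutoff_hz > 0)
  structure(list(order = order, cutoff_hz = cutoff_hz, family = "butterworth"),
            class = "filter_spec")
}

# steady-state initial conditions for a step input (direct form II transposed),
# so that DC passes through the recursion without a start-up transient
.filter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  b <- b / a[1]; a <- a / a[1]
  if (n == 1) return(numeric(0))
  comp <- rbind(-a[-1], cbind(diag(n - 2), 0))  # companion matrix of a
  IminusA <- diag(n - 1) - t(comp)
  B <- b[-1] - a[-1] * b[1]
  as.numeric(solve(IminusA, B))
}

.one_pass <- function(b, a, x, zi) .iir_df2t(b, a, x, zi * x[1])

#' Zero-phase Butterworth low-pass filter
#'
#' Applies the filter forward then backward so the net phase response is zero
#' and landmark timing is preserved. Edges are handled by odd-reflection
#' padding combined with steady-state initial conditions, which suppresses
#' start/end transients (a constant signal passes through unchanged to machine
#' precision). The pad length is sized from the filter's slowest pole so the
#' start-up transient decays below 1e-12 before the pad ends — at least
#' `3 * (order + 1)` samples.
#'
#' @param segment a [ppg_segment()] or numeric vector.
#' @param spec a [filter_spec()].
#' @param fs sampling frequency in Hz (taken from the segment if omitted).
#' @return object of the same type as `segment`, filtered.
#' @export
lowpass_zero_phase <- function(segment, spec = filter_spec(), fs = NULL) {
  is_seg <- inherits(segment, "ppg_segment")
  x <- as_segment_samples(segment)
  fs <- fs %||% (if (is_seg) segment$fs else NULL)
  if (is.null(fs)) stop2("fs must be supplied for a bare numeric vector")
  if (spec$cutoff_hz >= fs / 2)
    stop2("cutoff %g Hz is at or above Nyquist (%g Hz)", spec$cutoff_hz, fs / 2)
  bf <- signal::butter(spec$order, spec$cutoff_hz / (fs / 2), type = "low")
  b <- as.numeric(bf$b); a <- as.numeric(bf$a)
  # pad until the slowest pole has decayed below 1e-12
  pmax_mod <- max(Mod(polyroot(rev(a))))
  npad <- max(3 * (spec$order + 1),
              if (pmax_mod < 1) ceiling(log(1e-12) / log(pmax_mod)) else 200)
  if (length(x) <= max(3 * spec$order, npad))
    stop2("segment too short (%d samples) for order-%d zero-phase filtering",
          length(x), spec$order)
  zi <- .filter_zi(b, a)
  n <- length(x)
  # odd reflection about the end points
  front <- 2 * x[1] - x[(npad + 1):2]
  back <- 2 * x[n] - x[(n - 1):(n - npad)]
  ext <- c(front, x, back)
  y <- .one_pass(b, a, ext, zi)
  y <- rev(.one_pass(b, a, rev(y), zi))
  y <- y[(npad + 1):(npad + n)]
  if (is_seg) { segment$samples <- y; segment } else y
}

#' Variational mode decomposition
#'
#' Decomposes a real signal into `K` band-limited modes by the ADMM scheme:
#' spectral-domain Wiener-filter updates for the modes, power-weighted mean
#' frequency updates for the mode centers, and dual ascent (step `tau`) on the
#' reconstruction constraint. The signal is mirror-extended by half its length
#' on each side before the transform to reduce boundary splitting.
#'
#' @param samples numeric vector (length >= 16) or [ppg_segment()].
#' @param fs sampling frequency in Hz.
#' @param K number of modes (default 5).
#' @param alpha mode bandwidth penalty (default 2000); larger values give
#'   narrower-band modes.
#' @param tau dual-ascent step (default 0 = no strict reconstruction
#'   enforcement, robust to noise).
#' @param tol convergence tolerance on the summed relative mode change
#'   (default 1e-7).
#' @param max_iter iteration cap (default 500).
#' @param mirror mirror-extend before decomposing (default TRUE).
#' @return object of class `vmd_result`: `modes` (K x n matrix, rows ordered
#'   by ascending center frequency), `center_freqs` (Hz), `residual`
#'   (`samples - colSums(modes)`), `params`, `converged`, `iterations`.
#' @export
vmd_decompose <- function(samples, fs, K = 5, alpha = 2000, tau = 0,
                          tol = 1e-7, max_iter = 500, mirror = TRUE) {
  x <- as_segment_samples(samples)
  if (inherits(samples, "ppg_segment")) fs <- samples$fs
  if (K < 1) stop2("K must be >= 1")
  if (alpha <= 0) stop2("alpha must be > 0")
  n <- length(x)
  if (n < 16) stop2("VMD requires at least 16 samples")
  if (mirror) {
    h <- floor(n / 2)
    ext <- c(rev(x[1:h]), x, rev(x[(n - h + 1):n]))
  } else ext <- x
  if (length(ext) %% 2 == 1) ext <- c(ext, ext[length(ext)])
  res <- .vmd_core(ext, as.integer(K), alpha, tau, tol, as.integer(max_iter))
  off <- if (mirror) floor(n / 2) else 0
  modes <- t(res$modes[(off + 1):(off + n), , drop = FALSE])
  cf <- res$omega * fs
  ord <- order(cf)
  modes <- modes[ord, , drop = FALSE]
  cf <- cf[ord]
  if (!res$converged)
    warning(sprintf("VMD did not converge within %d iterations", max_iter))
  structure(list(modes = modes, center_freqs = cf,
                 residual = x - colSums(modes),
                 params = list(K = K, alpha = alpha, tau = tau, tol = tol,
                               max_iter = max_iter, fs = fs),
                 converged = res$converged, iterations = res$iterations),
            class = "vmd_result")
}

#' Remove low-frequency motion artifacts via VMD
#'
#' Decomposes the (already low-pass-filtered) segment with VMD and removes the
#' lowest-center-frequency mode only when it is both dominant and sub-respiratory:
#' relative energy above `energy_frac` AND center frequency below
#' `max_center_hz`. The default 0.1 Hz ceiling keeps respiratory-band content
#' (>= 0.083 Hz at RR = 5 breaths/min) intact. The decision is recorded on the
#' returned object.
#'
#' @param segment a [ppg_segment()] or numeric vector.
#' @param fs sampling frequency (taken from segment if omitted).
#' @param energy_frac minimum relative energy of the candidate mode (default 0.3).
#' @param max_center_hz maximum center frequency of a removable mode (default 0.1).
#' @param enabled set `FALSE` to pass the segment through untouched.
#' @param K,alpha,tau,tol,max_iter VMD parameters (see [vmd_decompose()]).
#' @return the segment (same type as input) with an `artifact_removed`
#'   attribute (logical) and, when input is a `ppg_segment`, fields
#'   `artifact_removed` and `vmd_converged`.
#' @export
remove_motion_artifacts <- function(segment, fs = NULL, energy_frac = 0.3,
                                    max_center_hz = 0.1, enabled = TRUE,
                                    K = 5, alpha = 2000, tau = 0, tol = 1e-7,
                                    max_iter = 500) {
  is_seg <- inherits(segment, "ppg_segment")
  x <- as_segment_samples(segment)
  fs <- fs %||% (if (is_seg) segment$fs else NULL)
  if (is.null(fs)) stop2("fs must be supplied for a bare numeric vector")
  removed <- FALSE
  converged <- TRUE
  if (enabled && any(x != 0) && sd(x) > 0) {
    # decompose the mean-removed signal: the DC level is not an artifact and
    # must not inflate the lowest mode's energy share
    mu <- mean(x)
    dec <- withCallingHandlers(
      vmd_decompose(x - mu, fs, K = K, alpha = alpha, tau = tau, tol = tol,
                    max_iter = max_iter),
      warning = function(w) invokeRestart("muffleWarning"))
    converged <- dec$converged
    energies <- rowSums(dec$modes^2)
    etot <- sum(energies)
    if (etot > 0) {
      lowest <- which.min(dec$center_freqs)
      if (energies[lowest] / etot > energy_frac &&
          dec$center_freqs[lowest] < max_center_hz) {
        x <- x - dec$modes[lowest, ]
        removed <- TRUE
      }
    }
  }
  if (is_seg) {
    segment$samples <- x
    segment$artifact_removed <- removed
    segment$vmd_converged <- converged
    attr(segment, "artifact_removed") <- removed
    segment
  } else {
    attr(x, "artifact_removed") <- removed
    x
  }
}

#' Preprocess a segment set (filter + artifact removal)
#'
#' Convenience wrapper applying [lowpass_zero_phase()] then
#' [remove_motion_artifacts()] to every segment.
#'
#' @param segments a `segment_set`.
#' @param spec a [filter_spec()].
#' @param ... passed to [remove_motion_artifacts()].
#' @return the preprocessed `segment_set`.
#' @export
preprocess_segments <- function(segments, spec = filter_spec(), ...) {
  stopifnot(inherits(segments, "segment_set"))
  segments$segments <- lapply(segments$segments, function(s) {
    remove_motion_artifacts(lowpass_zero_phase(s, spec), ...)
  })
  segments
}
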