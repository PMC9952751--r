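fs <- 125

test_that("a constant segment passes the zero-phase filter unchanged", {
  y <- lowpass_zero_phase(rep(3.7, 800), fs = fs)
  expect_lt(max(abs(y - 3.7)), 1e-9)
})

test_that("pass-band tone is preserved with zero lag, stop-band tone attenuated", {
  t <- (0:3999) / fs
  mid <- 500:3500                      # steady-state section
  s5 <- sin(2 * pi * 5 * t)
  y5 <- lowpass_zero_phase(s5, fs = fs)
  gain <- sd(y5[mid]) / sd(s5[mid])
  expect_gt(gain, 0.99)
  expect_lt(gain, 1.01)
  cc <- ccf(y5, s5, lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)

  s40 <- sin(2 * pi * 40 * t)
  y40 <- lowpass_zero_phase(s40, fs = fs)
  atten_db <- 20 * log10(sd(s40[mid]) / sd(y40[mid]))
  expect_gte(atten_db, 40)
  # analytic two-pass Butterworth magnitude is a lower bound: the bilinear
  # transform only steepens the response between cutoff and Nyquist
  analytic_db <- 2 * 10 * log10(1 + (40 / 25)^12)
  expect_gte(atten_db, analytic_db - 1)
})

test_that("filtering commutes with time reversal (zero-phase property)", {
  set.seed(5)
  for (i in 1:5) {
    x <- rnorm(1500) + sin(2 * pi * runif(1, 0.5, 10) * (1:1500) / fs)
    a <- lowpass_zero_phase(rev(x), fs = fs)
    b <- rev(lowpass_zero_phase(x, fs = fs))
    expect_lt(max(abs(a - b)), 1e-9)
  }
})

test_that("invalid filter setups are rejected", {
  expect_error(lowpass_zero_phase(rnorm(1000), filter_spec(cutoff_hz = 70), fs = fs),
               "Nyquist")
  expect_error(lowpass_zero_phase(rnorm(50), fs = fs), "too short")
})

test_that("VMD separates well-spaced tones and recovers center frequencies", {
  fs2 <- 50
  tt <- (0:(8 * fs2 - 1)) / fs2
  x <- sin(2 * pi * 1 * tt) + sin(2 * pi * 10 * tt)
  v <- vmd_decompose(x, fs2, K = 2, alpha = 2000)
  expect_equal(v$center_freqs[1], 1, tolerance = 0.2)
  expect_equal(v$center_freqs[2], 10, tolerance = 0.02)
  # FFT oracle: each mode's spectral peak sits at its center frequency
  for (k in 1:2) {
    pg <- periodogram_hann(v$modes[k, ], fs2)
    expect_equal(pg$freq[which.max(pg$power)], v$center_freqs[k],
                 tolerance = 0.2)
  }
  # sorted centers, within [0, fs/2]
  expect_true(!is.unsorted(v$center_freqs))
  expect_true(all(v$center_freqs >= 0 & v$center_freqs <= fs2 / 2))
})

test_that("a single tone is recovered by K = 1", {
  t <- (0:3999) / fs
  v <- vmd_decompose(sin(2 * pi * 5 * t), fs, K = 1)
  expect_equal(v$center_freqs, 5, tolerance = 0.2)
})

test_that("modes + residual reconstruct the input exactly", {
  set.seed(7)
  x <- rnorm(512)
  for (tau in c(0, 0.5)) {
    v <- suppressWarnings(vmd_decompose(x, 64, K = 3, tau = tau))
    err <- sum((x - colSums(v$modes) - v$residual)^2) / sum(x^2)
    expect_lt(err, 1e-6)
    expect_length(v$residual, length(x))
  }
})

test_that("VMD modes are band-limited around their centers for separated tones", {
  fs2 <- 40
  tt <- (0:(16 * fs2 - 1)) / fs2
  x <- sin(2 * pi * 2 * tt) + 0.8 * sin(2 * pi * 9 * tt) + 0.6 * sin(2 * pi * 16 * tt)
  K <- 3
  v <- vmd_decompose(x, fs2, K = K, alpha = 2000)
  for (k in 1:K) {
    pg <- periodogram_hann(v$modes[k, ], fs2)
    inb <- abs(pg$freq - v$center_freqs[k]) <= fs2 / (2 * K)
    expect_gte(sum(pg$power[inb]) / sum(pg$power), 0.9)
  }
})

test_that("VMD validates its inputs", {
  expect_error(vmd_decompose(rnorm(100), 50, K = 0), "K")
  expect_error(vmd_decompose(rnorm(100), 50, alpha = -1), "alpha")
  expect_error(vmd_decompose(rnorm(8), 50), "16 samples")
})

test_that("artifact removal leaves clean PPG untouched", {
  g <- clean_train(hr = 70, rr = 12, seed = 11)
  seg <- lowpass_zero_phase(g$segment)
  out <- remove_motion_artifacts(seg)
  expect_false(out$artifact_removed)
  rel <- sqrt(mean((out$samples - seg$samples)^2)) / sqrt(mean(seg$samples^2))
  expect_lt(rel, 0.05)
})

test_that("a dominant sub-respiratory drift is removed and correlation improves", {
  g <- clean_train(hr = 70, rr = 12, seed = 11)
  seg <- lowpass_zero_phase(g$segment)
  drift <- 3 * sin(2 * pi * 0.05 * (0:3999) / fs)
  corrupted <- seg
  corrupted$samples <- seg$samples + drift
  out <- remove_motion_artifacts(corrupted)
  expect_true(out$artifact_removed)
  expect_gt(cor(out$samples, g$truth$clean), cor(corrupted$samples, g$truth$clean))
  # idempotent: a second application changes nothing
  out2 <- remove_motion_artifacts(out)
  expect_false(out2$artifact_removed)
  expect_equal(out2$samples, out$samples)
})

test_that("degenerate segments pass through artifact removal unchanged", {
  z <- remove_motion_artifacts(rep(0, 4000), fs = fs)
  expect_true(all(z == 0))
  expect_false(attr(z, "artifact_removed"))
})

test_that("slow respiratory baseline at RR = 5 breaths/min is preserved", {
  g <- clean_train(hr = 70, rr = 5, seed = 12)
  out <- remove_motion_artifacts(lowpass_zero_phase(g$segment))
  expect_false(out$artifact_removed)
})
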