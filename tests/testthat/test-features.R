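test_that("the catalog has exactly 107 unique named features and is stable", {
  fc <- feature_catalog()
  expect_equal(nrow(fc), 107)
  expect_false(anyDuplicated(fc$name) > 0)
  expect_true(all(c("t1_tpi_ratio_mean", "max_frequency") %in% fc$name))
  expect_setequal(unique(fc$group),
                  c("time", "derivative", "frequency", "statistical"))
  expect_identical(fc, feature_catalog())   # deterministic across invocations
})

test_that("every extraction returns exactly the 107 catalog features", {
  fs <- 125
  inputs <- list(
    clean_train(seed = 13)$segment,                  # normal PPG
    sin(2 * pi * 1.2 * (0:3999) / fs),               # bare sine, no beats found
    rnorm(4000)                                      # noise
  )
  for (x in inputs) {
    v <- extract_features(x, fs = fs)
    expect_length(v, 107)
    expect_identical(names(v), feature_catalog()$name)
  }
  # constant segment: fiducial features missing, the rest still defined
  v0 <- extract_features(rep(2, 4000), fs = fs)
  expect_length(v0, 107)
  expect_true(is.na(v0["sys_amp_mean"]))
  expect_false(is.na(v0["sig_mean"]))
})

test_that("moment features match brute-force references", {
  set.seed(77)
  x <- rnorm(4000)^2 - 1
  v <- extract_features(x, fs = 125)
  n <- length(x); m <- sum(x) / n
  m2 <- sum((x - m)^2) / n; m3 <- sum((x - m)^3) / n; m4 <- sum((x - m)^4) / n
  expect_equal(unname(v["sig_mean"]), m, tolerance = 1e-10)
  expect_equal(unname(v["sig_var"]), m2, tolerance = 1e-10)
  expect_equal(unname(v["sig_sd"]), sqrt(m2), tolerance = 1e-10)
  expect_equal(unname(v["sig_skewness"]), m3 / m2^1.5, tolerance = 1e-10)
  expect_equal(unname(v["sig_kurtosis"]), m4 / m2^2, tolerance = 1e-10)
  expect_equal(unname(v["sig_rms"]), sqrt(sum(x^2) / n), tolerance = 1e-10)
})

test_that("a pure sine has population kurtosis 1.5 and the right dominant frequency", {
  fs <- 125
  x <- sin(2 * pi * 1.25 * (0:3999) / fs)   # integer period count
  v <- extract_features(x, fs = fs)
  m <- mean(x)
  brute <- mean((x - m)^4) / mean((x - m)^2)^2
  expect_equal(unname(v["sig_kurtosis"]), brute, tolerance = 1e-10)
  expect_equal(unname(v["sig_kurtosis"]), 1.5, tolerance = 1e-3 / 1.5)
  bin <- fs / 4000
  expect_lte(abs(v["cardiac_peak_freq"] - 1.25), bin)
  expect_lte(abs(v["max_frequency"] - 1.25), bin)
})

test_that("a synthetic 72 bpm train puts the cardiac peak at 1.2 Hz", {
  g <- generate_segment(synth_config(hr_bpm = 72, rr_bpm = 15, seed = 9))
  v <- extract_features(g$segment)
  expect_lte(abs(v["cardiac_peak_freq"] - 1.2), 125 / 4000)
  expect_lte(abs(v["resp_peak_freq"] - 0.25), 125 / 4000)
})

test_that("dimensionless features are invariant to amplitude scaling", {
  g <- clean_train(seed = 19)
  v1 <- extract_features(g$segment)
  v2 <- extract_features(2 * g$segment$samples, fs = 125)
  inv <- c("t1_tpi_ratio_mean", "b_a_mean", "dia_sys_ratio_mean",
           "sig_skewness", "sig_kurtosis", "spectral_entropy",
           "sig_shannon_entropy", "resp_band_ratio", "sig_hjorth_mobility")
  expect_lt(max(abs(v1[inv] - v2[inv])), 1e-9)
})

test_that("beat-statistic features are stable under sub-beat circular shifts", {
  g <- clean_train(hr = 64, seed = 23)
  x <- g$segment$samples
  v1 <- extract_features(x, fs = 125)
  shift <- 40   # about a third of a beat
  v2 <- extract_features(c(x[-seq_len(shift)], x[seq_len(shift)]), fs = 125)
  for (f in c("sys_amp_mean", "tpi_mean", "t1_tpi_ratio_mean", "width50_mean")) {
    expect_lt(abs(v2[f] - v1[f]) / abs(v1[f]), 0.02)
  }
})

test_that("the Shannon entropy uses 16 amplitude bins with base-2 logs", {
  # two-level signal split 50/50: entropy exactly 1 bit
  x <- rep(c(0, 1), 500)
  v <- extract_features(x, fs = 125)
  expect_equal(unname(v["sig_shannon_entropy"]), 1)
  # uniform coverage of all 16 bins approaches log2(16) = 4 bits
  u <- seq(0, 1, length.out = 1600)
  vu <- extract_features(u, fs = 125)
  expect_equal(unname(vu["sig_shannon_entropy"]), 4, tolerance = 0.01)
})

test_that("feature matrices stack rows with labels and flag missing columns", {
  corpus <- generate_corpus(10, seed = 31)
  fm <- build_matrix(preprocess_segments(corpus$segments))
  expect_equal(dim(fm$X), c(10, 107))
  expect_equal(fm$labels$rr,
               vapply(corpus$segments$segments, `[[`, 0, "rr_label"))
  expect_error(build_matrix(corpus$segments, vectors = list(rnorm(107))),
               "one feature vector per segment")
})

test_that("standardization parameters come from training rows only", {
  set.seed(41)
  X <- matrix(rnorm(200 * 5, mean = 3, sd = 2), 200)
  X[4, 2] <- NA
  tr <- 1:120; te <- 121:200
  imp <- fit_imputer(X, tr)
  Xi <- apply_imputer(imp, X)
  expect_false(anyNA(Xi))
  std <- fit_standardizer(Xi, tr)
  Z <- apply_standardizer(std, Xi)
  expect_lt(max(abs(colMeans(Z[tr, ]))), 1e-9)
  expect_lt(max(abs(apply(Z[tr, ], 2, sd) - 1)), 1e-9)
  # test rows keep the training transform, not their own
  expect_gt(max(abs(colMeans(Z[te, ]))), 1e-9)
  expect_equal(Z[te, ], apply_standardizer(std, Xi[te, ]))
})

test_that("feature matrices round-trip through CSV", {
  fm <- small_feature_matrix()
  path <- tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  back <- read_feature_matrix(path)
  expect_equal(back$X, fm$X, tolerance = 1e-12)
  expect_equal(back$labels$rr, fm$labels$rr, tolerance = 1e-12)
  unlink(path)
})
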