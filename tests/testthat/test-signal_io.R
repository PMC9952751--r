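test_that("segment counts follow the closed form across window geometries", {
  fs <- 125
  rec <- ppg_record(sin(seq_len(480 * fs) / 20), fs, "r480")
  expect_length(segment_record(rec, 32, 0.5)$segments, 29)

  rec1 <- ppg_record(rnorm(32 * fs), fs, "r32")
  expect_length(segment_record(rec1, 32, 0.5)$segments, 1)

  rec0 <- ppg_record(rnorm(31 * fs), fs, "r31")
  expect_warning(ss <- segment_record(rec0, 32, 0.5), "shorter")
  expect_length(ss$segments, 0)

  # property sweep: count = floor((T - w)/step) + 1, step = w(1 - overlap)
  set.seed(11)
  for (i in 1:25) {
    fs_i <- sample(c(50, 100, 125), 1)
    T_s <- runif(1, 10, 200)
    w <- sample(c(8, 16, 32), 1)
    ov <- sample(c(0, 0.25, 0.5, 0.75), 1)
    n_samp <- round(T_s * fs_i)
    rec_i <- ppg_record(rnorm(n_samp), fs_i)
    nwin <- round(w * fs_i)
    expected <- if (n_samp >= nwin) floor((n_samp - nwin) / (nwin * (1 - ov))) + 1 else 0
    got <- suppressWarnings(length(segment_record(rec_i, w, ov)$segments))
    expect_equal(got, expected,
                 info = sprintf("T=%.1f w=%d ov=%.2f fs=%d", T_s, w, ov, fs_i))
  }
})

test_that("consecutive segments advance by window * (1 - overlap)", {
  rec <- ppg_record(rnorm(300 * 125), 125)
  segs <- segment_record(rec, 32, 0.5)$segments
  starts <- vapply(segs, `[[`, 0, "start_time")
  expect_equal(diff(starts), rep(16, length(starts) - 1))
  expect_true(all(vapply(segs, function(s) length(s$samples), 0L) == 4000))
})

test_that("labels are the mean of in-window reference values", {
  fs <- 125
  ref <- data.frame(time = 0:99, rr = 15, spo2 = 97)
  rec <- ppg_record(rnorm(100 * fs), fs, reference = ref)
  segs <- attach_labels(segment_record(rec, 32, 0.5), rec)
  expect_true(all(vapply(segs$segments, `[[`, 0, "rr_label") == 15))

  # two in-window values 10 and 20 average to 15
  ref2 <- data.frame(time = c(10, 20), rr = c(10, 20))
  rec2 <- ppg_record(rnorm(40 * fs), fs, reference = ref2)
  segs2 <- attach_labels(segment_record(rec2, 32, 0.5), rec2)
  expect_equal(segs2$segments[[1]]$rr_label, 15)
  # no spo2 column: label stays absent
  expect_true(is.na(segs2$segments[[1]]$spo2_label))

  # reference points all outside the window -> unlabeled + flag
  ref3 <- data.frame(time = 35, rr = 12)
  rec3 <- ppg_record(rnorm(40 * fs), fs, reference = ref3)
  segs3 <- attach_labels(segment_record(rec3, 32, 0.5), rec3)
  expect_true(is.na(segs3$segments[[1]]$rr_label))
  expect_true(segs3$segments[[1]]$unlabeled)

  # empty reference -> warning, all unlabeled
  rec4 <- ppg_record(rnorm(40 * fs), fs,
                     reference = data.frame(time = numeric(), rr = numeric()))
  expect_warning(segs4 <- attach_labels(segment_record(rec4, 32, 0.5), rec4),
                 "empty reference")
  expect_true(segs4$segments[[1]]$unlabeled)
})

test_that("segment sets round-trip through CSV bit-exactly", {
  ref <- data.frame(time = seq(0, 95, 5), rr = runif(20, 5, 25),
                    spo2 = runif(20, 84, 100))
  rec <- ppg_record(rnorm(100 * 50), 50, "rt", reference = ref)
  segs <- attach_labels(segment_record(rec, 32, 0.5), rec)
  path <- tempfile(fileext = ".csv")
  write_segments(segs, path)
  back <- read_segments(path)
  expect_length(back$segments, length(segs$segments))
  for (i in seq_along(segs$segments)) {
    expect_identical(back$segments[[i]]$samples, segs$segments[[i]]$samples)
    expect_equal(back$segments[[i]]$rr_label, segs$segments[[i]]$rr_label)
    expect_equal(back$segments[[i]]$spo2_label, segs$segments[[i]]$spo2_label)
  }
  unlink(c(path, paste0(path, ".json")))
})

test_that("csv records are read with fs from the time axis or override", {
  path <- tempfile(fileext = ".csv")
  n <- 60000
  write.csv(data.frame(time = (0:(n - 1)) / 125, ppg = sin(1:n / 30)), path,
            row.names = FALSE)
  rec <- read_record(path, "csv")
  expect_equal(rec$duration, 480)
  expect_equal(rec$fs, 125)
  unlink(path)

  # explicit fs, no time column
  path2 <- tempfile(fileext = ".csv")
  write.csv(data.frame(ppg = rnorm(1000)), path2, row.names = FALSE)
  expect_equal(read_record(path2, "csv", fs = 100)$duration, 10)
  unlink(path2)
})

test_that("non-finite samples are rejected with the offending row named", {
  path <- tempfile(fileext = ".csv")
  v <- rnorm(100); v[37] <- NA
  write.csv(data.frame(ppg = v), path, row.names = FALSE)
  expect_error(read_record(path, "csv", fs = 50), "row 37")
  unlink(path)
  expect_error(read_record(tempfile(), "csv", fs = 50), "not found")
})

test_that("WFDB format-16 records are read via the text header", {
  stem <- tempfile()
  fs <- 125; n <- 1000
  pleth <- round(sin(2 * pi * 1.2 * (0:(n - 1)) / fs) * 400 + 512)
  ecg <- round(rnorm(n, 0, 50))
  writeLines(c(sprintf("%s 2 125 %d", basename(stem), n),
               sprintf("%s.dat 16 1024(512)/NU 10 0 0 0 0 PLETH", basename(stem)),
               sprintf("%s.dat 16 200/mV 12 0 0 0 0 II", basename(stem)),
               "# synthetic fixture"),
             paste0(stem, ".hea"))
  interleaved <- as.integer(rbind(pleth, ecg))
  writeBin(interleaved, paste0(stem, ".dat"), size = 2, endian = "little")
  rec <- read_record(stem, "wfdb")
  expect_equal(rec$fs, 125)
  expect_length(rec$samples, n)
  # gain 1024, baseline 512 undone
  expect_equal(rec$samples, (pleth - 512) / 1024, tolerance = 1e-12)
  expect_error(read_record(stem, "wfdb", channel = "RESP"), "channel")
  unlink(paste0(stem, c(".hea", ".dat")))
})

test_that("label and amplitude validation reject out-of-range values", {
  expect_error(ppg_segment(rnorm(10), 125, rr_label = 150), "120")
  expect_error(ppg_segment(rnorm(10), 125, spo2_label = 101), "100")
  expect_error(ppg_record(numeric(), 125), "empty")
  expect_error(ppg_record(rnorm(10), -1), "positive")
  expect_error(ppg_record(rnorm(10), 125,
                          reference = data.frame(time = c(1, 1), rr = c(5, 6))),
               "increasing")
})

test_that("the optional quality screen flags flat-lined and clipped windows", {
  corpus <- generate_corpus(6, seed = 21)
  segs <- corpus$segments
  segs$segments[[2]]$samples <- rep(0.5, 4000)          # flat line
  clipped <- segs$segments[[3]]$samples
  clipped[clipped > quantile(clipped, 0.7)] <- max(clipped)  # rail
  segs$segments[[3]]$samples <- clipped
  keep <- quality_screen(segs)
  expect_false(keep[2])
  expect_false(keep[3])
  expect_true(all(keep[-c(2, 3)]))
})
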