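# Record and segment containers, file readers, windowing and label attachment.

#' Construct a PPG record
#'
#' @param samples numeric vector of PPG amplitudes (arbitrary units); must be
#'   finite and non-empty.
#' @param fs sampling frequency in Hz (> 0).
#' @param record_id opaque identifier string.
#' @param reference optional data frame of reference vitals with columns
#'   `time` (seconds from record start, strictly increasing) and any of
#'   `rr` (breaths/min), `spo2` (percent).
#' @return an object of class `ppg_record`.
#' @export
ppg_record <- function(samples, fs, record_id = "record", reference = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) == 0) stop2("record '%s': samples are empty", record_id)
  bad <- which(!is.finite(samples))
  if (length(bad) > 0)
    stop2("record '%s': non-finite sample at row %d", record_id, bad[1])
  if (!is.numeric(fs) || length(fs) != 1 || !is.finite(fs) || fs <= 0)
    stop2("record '%s': fs must be a positive number", record_id)
  duration <- length(samples) / fs
  if (!is.null(reference)) {
    reference <- as.data.frame(reference)
    if (!"time" %in% names(reference))
      stop2("reference series needs a 'time' column")
    if (any(diff(reference$time) <= 0))
      stop2("reference timestamps must be strictly increasing")
    if (any(reference$time < 0 | reference$time > duration))
      stop2("reference timestamps must lie within [0, %g] s", duration)
  }
  structure(list(samples = samples, fs = fs, record_id = record_id,
                 reference = reference, duration = duration),
            class = "ppg_record")
}

#' @export
print.ppg_record <- function(x, ...) {
  cat(sprintf("<ppg_record '%s'>: %d samples @ %g Hz (%.1f s), %s reference rows\n",
              x$record_id, length(x$samples), x$fs, x$duration,
              if (is.null(x$reference)) "no" else nrow(x$reference)))
  invisible(x)
}

#' Construct a PPG segment
#'
#' A fixed-length window cut from a record, with optional reference labels.
#' Windows are half-open `[start, start + window)`; sample indices are 0-based
#' in the time convention (`start_time` is the time of the first sample).
#'
#' @param samples numeric vector.
#' @param fs sampling frequency in Hz.
#' @param start_time seconds from record start.
#' @param rr_label reference respiration rate (breaths/min) or `NA`.
#' @param spo2_label reference SpO2 (percent) or `NA`.
#' @param record_id source record identifier.
#' @return an object of class `ppg_segment`.
#' @export
ppg_segment <- function(samples, fs, start_time = 0, rr_label = NA_real_,
                        spo2_label = NA_real_, record_id = "segment") {
  if (!is.na(rr_label) && (rr_label < 0 || rr_label > 120))
    stop2("rr_label %g outside [0, 120] breaths/min", rr_label)
  if (!is.na(spo2_label) && (spo2_label < 0 || spo2_label > 100))
    stop2("spo2_label %g outside [0, 100] %%", spo2_label)
  structure(list(samples = as.numeric(samples), fs = fs,
                 start_time = start_time, rr_label = rr_label,
                 spo2_label = spo2_label, record_id = record_id),
            class = "ppg_segment")
}

as_segment_samples <- function(x) {
  if (inherits(x, "ppg_segment")) x$samples else as.numeric(x)
}

#' Read a PPG record from disk
#'
#' Two formats are supported. `csv`: a table with a PPG column and either a
#' time column or an `fs` override; an optional separate numerics CSV supplies
#' the reference RR/SpO2 series. `wfdb`: a PhysioNet-style text header
#' (`<record>.hea`) plus a format-16 (little-endian int16) signal file; the
#' channel whose name matches `channel` (default `"PLETH"`) is read.
#'
#' @param path path to the CSV file or WFDB record stem (no extension).
#' @param format `"csv"` or `"wfdb"`.
#' @param fs sampling frequency override in Hz (required for csv without a
#'   time column).
#' @param ppg_col,time_col CSV column names for the PPG signal and time axis.
#' @param numerics optional path to a CSV of reference vitals with columns
#'   `time` plus any of `rr`/`spo2` (case-insensitive; `RESP` and `SpO2`
#'   PhysioNet-style headers are also recognized).
#' @param channel WFDB signal name to extract.
#' @param record_id identifier; defaults to the file stem.
#' @return a [ppg_record()].
#' @export
read_record <- function(path, format = c("csv", "wfdb"), fs = NULL,
                        ppg_col = "ppg", time_col = "time", numerics = NULL,
                        channel = "PLETH", record_id = NULL) {
  format <- match.arg(format)
  if (format == "csv") {
    if (!file.exists(path)) stop2("file not found: %s", path)
    tab <- read.csv(path, check.names = FALSE)
    names(tab) <- trimws(names(tab))
    if (!ppg_col %in% names(tab))
      stop2("column '%s' not found in %s (have: %s)", ppg_col, path,
            paste(names(tab), collapse = ", "))
    samples <- tab[[ppg_col]]
    if (is.null(fs)) {
      if (!time_col %in% names(tab))
        stop2("fs not given and no '%s' column to infer it from", time_col)
      dt <- diff(tab[[time_col]])
      if (any(!is.finite(dt)) || any(dt <= 0))
        stop2("time column is not strictly increasing")
      fs <- 1 / median(dt)
    }
    rid <- record_id %||% sub("\\.[^.]*$", "", basename(path))
    reference <- if (!is.null(numerics)) read_numerics(numerics) else NULL
    ppg_record(samples, fs, rid, reference)
  } else {
    read_wfdb_record(path, channel = channel, record_id = record_id,
                     numerics = numerics)
  }
}

read_numerics <- function(path) {
  if (!file.exists(path)) stop2("numerics file not found: %s", path)
  tab <- read.csv(path, check.names = FALSE)
  nm <- tolower(trimws(names(tab)))
  pick <- function(cands) {
    i <- which(nm %in% cands)
    if (length(i) > 0) tab[[i[1]]] else NULL
  }
  time <- pick(c("time", "time [s]", "t"))
  if (is.null(time)) stop2("numerics file %s has no time column", path)
  out <- data.frame(time = time)
  rr <- pick(c("rr", "resp", "resp rate", "rr [bpm]"))
  spo2 <- pick(c("spo2", "spo2 [%]", "sao2"))
  if (!is.null(rr)) out$rr <- rr
  if (!is.null(spo2)) out$spo2 <- spo2
  out
}

# Minimal WFDB reader: text .hea header + single format-16 .dat file.
read_wfdb_record <- function(stem, channel = "PLETH", record_id = NULL,
                             numerics = NULL) {
  hea <- paste0(stem, ".hea")
  if (!file.exists(hea)) stop2("WFDB header not found: %s", hea)
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(top) < 3) stop2("unparseable WFDB header line: %s", lines[1])
  n_sig <- as.integer(top[2])
  fs <- as.numeric(sub("/.*", "", top[3]))
  if (!is.finite(fs) || fs <= 0) stop2("WFDB header has no usable fs")
  n_samp <- if (length(top) >= 4) as.integer(top[4]) else NA_integer_
  sig <- lines[2:(1 + n_sig)]
  fields <- lapply(sig, function(l) strsplit(trimws(l), "\\s+")[[1]])
  fmts <- vapply(fields, `[`, "", 2)
  if (any(sub("x.*|:.*|\\+.*", "", fmts) != "16"))
    stop2("only format-16 WFDB signals are supported")
  snames <- vapply(fields, function(f) f[length(f)], "")
  ch <- match(channel, snames)
  if (is.na(ch)) stop2("channel '%s' not in WFDB record (have: %s)",
                       channel, paste(snames, collapse = ", "))
  datfile <- file.path(dirname(hea), fields[[1]][1])
  if (!file.exists(datfile)) stop2("WFDB signal file not found: %s", datfile)
  raw <- readBin(datfile, "integer", n = file.size(datfile) / 2, size = 2,
                 signed = TRUE, endian = "little")
  mat <- matrix(raw, ncol = n_sig, byrow = TRUE)
  if (!is.na(n_samp) && nrow(mat) > n_samp) mat <- mat[seq_len(n_samp), , drop = FALSE]
  gp <- strsplit(fields[[ch]][3], "[(/]")[[1]]
  gain <- suppressWarnings(as.numeric(gp[1]))
  if (!is.finite(gain) || gain == 0) gain <- 200
  baseline <- suppressWarnings(as.numeric(sub("\\).*", "", gp[2])))
  if (!is.finite(baseline)) baseline <- 0
  samples <- (mat[, ch] - baseline) / gain
  rid <- record_id %||% basename(stem)
  reference <- if (!is.null(numerics)) read_numerics(numerics) else NULL
  ppg_record(samples, fs, rid, reference)
}

#' Window a record into overlapping fixed-length segments
#'
#' Tiles the record with windows of `window_s` seconds advancing by
#' `window_s * (1 - overlap)`; a trailing partial window is dropped (padding
#' would distort spectral features). For a record of `T` seconds the segment
#' count is `floor((T - window_s) / step) + 1` when `T >= window_s`, else 0.
#'
#' @param record a [ppg_record()].
#' @param window_s window length in seconds (default 32).
#' @param overlap overlap fraction in `[0, 1)` (default 0.5).
#' @return an object of class `segment_set`: list with `segments` (list of
#'   [ppg_segment()]) and `provenance`.
#' @export
segment_record <- function(record, window_s = 32, overlap = 0.5) {
  stopifnot(inherits(record, "ppg_record"))
  if (overlap < 0 || overlap >= 1) stop2("overlap must be in [0, 1)")
  nwin <- round(window_s * record$fs)
  if (nwin < 2) stop2("window of %g s spans fewer than 2 samples", window_s)
  step <- nwin * (1 - overlap)
  n <- length(record$samples)
  starts <- integer(0)
  if (n >= nwin) {
    k <- floor((n - nwin) / step) + 1
    starts <- round((seq_len(k) - 1) * step)
  } else {
    warning(sprintf("record '%s' (%.1f s) shorter than one %g s window",
                    record$record_id, record$duration, window_s))
  }
  segments <- lapply(starts, function(s0) {
    ppg_segment(record$samples[(s0 + 1):(s0 + nwin)], record$fs,
                start_time = s0 / record$fs, record_id = record$record_id)
  })
  structure(list(segments = segments,
                 provenance = list(record_ids = record$record_id,
                                   window_s = window_s, overlap = overlap,
                                   fs = record$fs)),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set>: %d segments (window %g s, overlap %g)\n",
              length(x$segments), x$provenance$window_s, x$provenance$overlap))
  invisible(x)
}

#' Attach reference labels to segments
#'
#' Each segment's RR / SpO2 label is a summary of the reference values whose
#' timestamps fall inside the half-open window `[start, start + window)`.
#' Segments with no in-window reference points stay unlabeled and are flagged.
#'
#' @param segments a `segment_set`.
#' @param record the source [ppg_record()] carrying the reference series.
#' @param rule label summary: `"mean"` (default), `"median"`, or
#'   `"midpoint"` (reference value nearest the window midpoint).
#' @return the `segment_set` with `rr_label`/`spo2_label` filled in and an
#'   `unlabeled` logical attribute per segment.
#' @export
attach_labels <- function(segments, record, rule = c("mean", "median", "midpoint")) {
  stopifnot(inherits(segments, "segment_set"), inherits(record, "ppg_record"))
  rule <- match.arg(rule)
  ref <- record$reference
  if (is.null(ref) || nrow(ref) == 0) {
    warning("record has an empty reference series; all segments unlabeled")
    segments$segments <- lapply(segments$segments, function(s) {
      s$unlabeled <- TRUE; s
    })
    return(segments)
  }
  window_s <- segments$provenance$window_s
  summarize <- function(v, tt, mid) {
    if (length(v) == 0) return(NA_real_)
    switch(rule,
           mean = mean(v),
           median = median(v),
           midpoint = v[which.min(abs(tt - mid))])
  }
  segments$segments <- lapply(segments$segments, function(s) {
    inw <- ref$time >= s$start_time & ref$time < s$start_time + window_s
    mid <- s$start_time + window_s / 2
    if ("rr" %in% names(ref))
      s$rr_label <- summarize(ref$rr[inw], ref$time[inw], mid)
    if ("spo2" %in% names(ref))
      s$spo2_label <- summarize(ref$spo2[inw], ref$time[inw], mid)
    s$unlabeled <- !any(inw)
    s
  })
  segments
}

#' Serialize a segment set to CSV (+ JSON provenance sidecar)
#'
#' One row per sample in long form (`segment`, `start_time`, `rr_label`,
#' `spo2_label`, `sample_idx`, `value`); full double precision is preserved so
#' the round trip is bit-exact.
#'
#' @param segments a `segment_set`.
#' @param path output CSV path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  stopifnot(inherits(segments, "segment_set"))
  rows <- lapply(seq_along(segments$segments), function(i) {
    s <- segments$segments[[i]]
    data.frame(segment = i, record_id = s$record_id,
               start_time = s$start_time, fs = s$fs,
               rr_label = s$rr_label, spo2_label = s$spo2_label,
               sample_idx = seq_along(s$samples) - 1L, value = s$samples)
  })
  tab <- do.call(rbind, rows)
  # full binary precision via format(digits = 17)
  tab$value <- format(tab$value, digits = 17, scientific = TRUE, trim = TRUE)
  write.csv(tab, path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(segments$provenance, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a segment set written by [write_segments()]
#'
#' @param path CSV path.
#' @return a `segment_set`.
#' @export
read_segments <- function(path) {
  tab <- read.csv(path)
  prov_path <- paste0(path, ".json")
  prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path, simplifyVector = TRUE)
          else list()
  segs <- lapply(split(tab, tab$segment), function(d) {
    d <- d[order(d$sample_idx), ]
    ppg_segment(d$value, fs = d$fs[1], start_time = d$start_time[1],
                rr_label = d$rr_label[1], spo2_label = d$spo2_label[1],
                record_id = as.character(d$record_id[1]))
  })
  structure(list(segments = unname(segs), provenance = prov),
            class = "segment_set")
}

#' Optional flat-line / clipping screen
#'
#' Disabled by default in the pipeline; flags segments whose amplitude range
#' collapses (flat line) or that saturate at their extremes for a sustained
#' fraction of samples (clipping).
#'
#' @param segments a `segment_set`.
#' @param min_range minimum peak-to-peak range relative to the median segment
#'   range across the set.
#' @param max_rail_frac maximum fraction of samples allowed to sit at the
#'   segment's min or max value.
#' @return logical vector, `TRUE` = keep.
#' @export
quality_screen <- function(segments, min_range = 0.05, max_rail_frac = 0.05) {
  rngs <- vapply(segments$segments, function(s) diff(range(s$samples)), 0)
  med <- median(rngs)
  vapply(seq_along(segments$segments), function(i) {
    s <- segments$segments[[i]]
    if (med > 0 && rngs[i] < min_range * med) return(FALSE)
    rail <- mean(s$samples == min(s$samples) | s$samples == max(s$samples))
    rail <= max_rail_frac
  }, TRUE)
}
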