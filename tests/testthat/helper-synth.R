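# Shared fixtures: small deterministic synthetic signals and a cached
# mini-corpus feature matrix (built once per test run).

clean_train <- function(hr = 60, rr = 15, seed = 101, ...) {
  generate_segment(synth_config(hr_bpm = hr, rr_bpm = rr, fm = 0,
                                noise_snr_db = Inf, artifact_rate_per_min = 0,
                                seed = seed, ...))
}

.fixture_env <- new.env(parent = emptyenv())

# 60-segment noisy corpus -> feature matrix, shared by CV-level tests
small_feature_matrix <- function() {
  if (is.null(.fixture_env$fm)) {
    corpus <- generate_corpus(60, seed = 404)
    segs <- preprocess_segments(corpus$segments)
    .fixture_env$fm <- pipeline_features(segs)
  }
  .fixture_env$fm
}

expect_no_na <- function(x) expect_false(anyNA(x))
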