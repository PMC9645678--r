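# Shared fixtures, built once per test run. Everything is generated in code;
# sizes are kept small so the whole suite stays fast.

.fixtures <- new.env(parent = emptyenv())

# a single short subject with default-strength signal
fixture_subject <- function() {
  if (is.null(.fixtures$subject)) {
    proto <- default_protocol(smoking_session_duration_s = 60,
                              nonsmoking_duration_s = 40,
                              eating_duration_s = 60)
    .fixtures$subject <- generate_subject(proto, easy_generator_params(seed = 42),
                                          subject_id = "S01", seed = 42)
  }
  .fixtures$subject
}

# small easy cohort for classifier/evaluation tests (4 subjects, ~7 min each)
fixture_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    proto <- default_protocol(smoking_session_duration_s = 60,
                              nonsmoking_duration_s = 40,
                              eating_duration_s = 60)
    .fixtures$cohort <- generate_cohort(4, proto, easy_generator_params(seed = 7))
  }
  .fixtures$cohort
}

# featurized + standardized single-subject window set (reduced spectrograms)
fixture_features <- function() {
  if (is.null(.fixtures$features)) {
    s <- fixture_subject()
    ws <- label_windows(segment(s$recording), s$log)
    fs <- featurize(ws, s$recording,
                    c(imu_channels(), paste0("semg", c(6, 1, 7, 4, 5))),
                    reduced_spectrogram_config())
    fs <- apply_standardizer(fs, fit_standardizer(fs))
    .fixtures$features <- list(ws = ws, fs = fs, x = flatten_tensors(fs))
  }
  .fixtures$features
}

with_seed_local <- function(seed, code) withr::with_seed(seed, code)

expect_same_numbers <- function(a, b, tol = 1e-10) {
  expect_equal(as.numeric(a), as.numeric(b), tolerance = tol)
}
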