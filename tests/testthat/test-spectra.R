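test_that("STFT frame count and bin count follow the configured geometry", {
  cfg <- spectrogram_config()   # 512-pt FFT, 256 Hamming, 95% overlap
  x <- rnorm(2000)
  m <- stft_magnitude(x, cfg)
  # hop = round(256 * 0.05) = 13; floor((2000 - 256)/13) + 1 = 135 frames
  expect_equal(dim(m), c(257L, 135L))
  expect_error(stft_magnitude(rnorm(100), cfg), "shorter")
})

test_that("frame count formula matches brute-force enumeration of frame starts", {
  set.seed(33)
  for (r in 1:40) {
    L <- sample(8:64, 1)
    ov <- runif(1, 0, 0.9)
    n <- L + sample(0:500, 1)
    cfg <- spectrogram_config(n_fft = 2^ceiling(log2(L)), stft_window_len = L,
                              overlap_fraction = ov, target_freq_bins = 4,
                              target_time_bins = 4)
    hop <- max(1, round(L * (1 - ov)))
    starts <- seq(1, n - L + 1, by = hop)   # oracle enumeration
    expect_equal(ncol(stft_magnitude(rnorm(n), cfg)), length(starts))
  }
})

test_that("a pure tone lands in the nearest frequency bin (direct DFT oracle)", {
  cfg <- spectrogram_config()
  fs <- 200
  t <- (0:1999) / fs
  x <- sin(2 * pi * 50 * t)
  m <- stft_magnitude(x, cfg)
  peak_bins <- apply(m, 2, which.max)
  # bin spacing fs/n_fft = 0.390625 Hz; expected bin index for 50 Hz
  expected_bin <- round(50 / (fs / cfg$n_fft)) + 1L
  expect_true(all(peak_bins == expected_bin))
  # oracle: direct DFT of the first tapered frame
  frame <- x[1:256] * (0.54 - 0.46 * cos(2 * pi * (0:255) / 255))
  dft <- abs(fft(c(frame, rep(0, 256))))[1:257]
  expect_equal(which.max(dft), expected_bin)
})

test_that("silent input maps to the dB floor after log scaling", {
  cfg <- spectrogram_config()
  m <- stft_magnitude(numeric(2000), cfg)
  db <- magnitude_to_db(m, cfg$db_floor)
  expect_true(all(db == cfg$db_floor))
  expect_true(all(is.finite(db)))
})

test_that("conform_shape maps raw arrays onto the fixed image grid", {
  cfg <- spectrogram_config()   # targets 256 x 112
  raw <- matrix(rnorm(257 * 135), 257, 135)
  out <- conform_shape(raw, cfg)
  expect_equal(dim(out), c(256L, 112L))
  # identity when already conformed
  ok <- matrix(rnorm(256 * 112), 256, 112)
  expect_identical(conform_shape(ok, cfg), ok)
  # interpolation preserves constants
  const <- matrix(3.5, 257, 50)
  expect_true(all(abs(conform_shape(const, cfg) - 3.5) < 1e-12))
  expect_error(conform_shape(matrix(0, 100, 10), cfg), "fewer")
})

test_that("featurize stacks channels in order with the contracted shape", {
  s <- fixture_subject()
  ws <- label_windows(segment(s$recording), s$log)
  cfg <- reduced_spectrogram_config()

  f8 <- featurize(ws[1:11, ], s$recording, semg_channels(), cfg)
  expect_equal(dim(f8$values), c(8L, 8L, 8L, 11L))
  expect_length(f8, 11L)

  mixed <- c(paste0("semg", c(6, 1, 7, 4, 5)), imu_channels())
  f11 <- featurize(ws[1:3, ], s$recording, mixed, cfg)
  expect_equal(dim(f11$values)[3], 11L)
  expect_equal(f11$channels, mixed)

  expect_error(featurize(ws[1:2, ], s$recording, "semg9", cfg), "unknown channel")
  expect_error(featurize(ws[1:2, ], s$recording, character(0), cfg), "non-empty")
  expect_error(featurize(ws[1:2, ], s$recording, c("semg1", "semg1"), cfg), "duplicate")
})

test_that("featurize equals the single-channel STFT path (batching oracle)", {
  s <- fixture_subject()
  ws <- label_windows(segment(s$recording), s$log)[1:5, ]
  cfg <- reduced_spectrogram_config()
  fs <- featurize(ws, s$recording, c("semg3", "gyro_y"), cfg)
  for (i in c(1L, 4L)) {
    x <- recording_channel(s$recording, "semg3")[ws$start_sample[i]:ws$end_sample[i]]
    ref <- conform_shape(magnitude_to_db(stft_magnitude(x, cfg), cfg$db_floor), cfg)
    expect_equal(fs$values[, , 1, i], ref, tolerance = 1e-12)
  }
})

test_that("shape contract holds for arbitrary window lengths", {
  cfg <- reduced_spectrogram_config()
  set.seed(5)
  for (len in c(16, 17, 100, 333, 2000)) {
    m <- conform_shape(stft_magnitude(rnorm(len), cfg), cfg)
    expect_equal(dim(m), c(8L, 8L))
  }
})

test_that("magnitudes scale monotonically with signal amplitude", {
  cfg <- reduced_spectrogram_config()
  set.seed(6)
  x <- rnorm(400)
  m1 <- stft_magnitude(x, cfg)
  m2 <- stft_magnitude(2.5 * x, cfg)
  expect_true(all(m2 >= m1 - 1e-12))
})

test_that("standardization is an exact per-channel z-score of the fit set", {
  f <- fixture_features()
  v <- f$fs$values
  for (c in seq_len(dim(v)[3])) {
    expect_lt(abs(mean(v[, , c, ])), 1e-8)
    expect_lt(abs(stats::sd(v[, , c, ]) - 1), 1e-6)
  }
})
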