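test_that("puff trains respect session bounds, spacing and determinism", {
  params <- generator_params(seed = 1)

  # degenerate session
  expect_equal(nrow(with_seed_local(1, puff_train(10, 10, params))), 0L)
  expect_equal(nrow(with_seed_local(1, puff_train(5, 6, params))), 0L)

  # a 267 s session with 2-4 s puffs every 20-40 s: cycle length lies in
  # [22, 44] s, so enumeration of extreme draws bounds the count to [6, 13]
  counts <- vapply(1:25, function(s) {
    iv <- with_seed_local(s, puff_train(0, 267, params))
    expect_true(all(iv$start_s >= 0) && all(iv$end_s <= 267))
    expect_true(all(diff(as.vector(t(iv[, c("start_s", "end_s")]))) > 0))
    nrow(iv)
  }, 0L)
  expect_true(all(counts >= 6 & counts <= 13))

  # same seed -> identical intervals
  expect_identical(with_seed_local(3, puff_train(0, 267, params)),
                   with_seed_local(3, puff_train(0, 267, params)))
})

test_that("generated subjects match their protocol and physical contracts", {
  s <- fixture_subject()
  rec <- s$recording; log <- s$log

  expect_s3_class(rec, "sensor_recording")
  expect_equal(sum(log$activity %in% smoking_classes()), 4L)
  expect_equal(nrow(log), 10L)
  expect_equal(recording_duration(rec), sum(log$end_s - log$start_s))

  # 8-bit clipping contract
  expect_true(all(rec$semg >= -128 & rec$semg <= 127))
  expect_type(rec$semg[1], "integer")

  # all channel arrays share n_samples
  expect_equal(nrow(rec$accel), nrow(rec$semg))
  expect_equal(nrow(rec$gyro), nrow(rec$semg))

  # empty protocol is unusable
  expect_error(generate_subject(structure(data.frame(), class = c("activity_protocol", "data.frame")),
                                generator_params()), "empty protocol")
})

test_that("gyro magnitude is elevated inside puff gestures", {
  s <- fixture_subject()
  rec <- s$recording
  params <- easy_generator_params(seed = 42)
  # regenerate the puff intervals of the seeded realization via the envelope:
  # use smoking sessions and compare in-session vs resting gyro RMS
  smk <- s$log[s$log$activity %in% smoking_classes(), ]
  rest <- s$log[s$log$activity == "resting", ]
  tt <- (seq_len(nrow(rec$semg)) - 1) / rec$sample_rate_hz
  gmag <- sqrt(rowSums(rec$gyro^2))
  in_smk <- rep(FALSE, length(tt))
  for (i in seq_len(nrow(smk))) in_smk <- in_smk | (tt >= smk$start_s[i] & tt < smk$end_s[i])
  in_rest <- tt >= rest$start_s[1] & tt < rest$end_s[1]
  expect_gt(sqrt(mean(gmag[in_smk]^2)), sqrt(mean(gmag[in_rest]^2)))
})

test_that("sEMG power during smoking exceeds resting power on active channels", {
  s <- fixture_subject()
  rec <- s$recording
  prof <- default_activation_profile()
  smk <- s$log[s$log$activity == "smoking_sitting", ]
  rest <- s$log[s$log$activity == "resting", ]
  fs <- rec$sample_rate_hz
  smk_idx <- (round(smk$start_s * fs) + 1):(round(smk$end_s * fs))
  rest_idx <- (round(rest$start_s * fs) + 1):(round(rest$end_s * fs))
  for (c in which(prof["smoking_sitting", ] > 0)) {
    expect_gt(mean(rec$semg[smk_idx, c]^2), mean(rec$semg[rest_idx, c]^2))
  }
})

test_that("activity log covers the full recording span without overlap", {
  s <- fixture_subject()
  log <- s$log
  expect_equal(log$start_s[1], 0)
  expect_equal(log$start_s[-1], log$end_s[-nrow(log)])  # gapless protocol
  expect_true(all(log$end_s > log$start_s))
})

test_that("cohorts are seeded, unique and subject-variable", {
  proto <- default_protocol(smoking_session_duration_s = 30,
                            nonsmoking_duration_s = 20, eating_duration_s = 30)
  params <- generator_params(seed = 9)
  a <- generate_cohort(3, proto, params)
  b <- generate_cohort(3, proto, params)
  expect_identical(a, b)
  ids <- vapply(a, function(s) s$recording$subject_id, "")
  expect_equal(anyDuplicated(ids), 0L)
  # different sub-seeds give different recordings
  expect_false(identical(a[[1]]$recording$semg, a[[2]]$recording$semg))
  expect_error(generate_cohort(1, proto, params), "at least 2")
})

test_that("parameter and protocol validation rejects bad configurations", {
  expect_error(generator_params(baseline_noise_sd = -1), "positive")
  expect_error(generator_params(puff_duration_s = c(4, 2)), "range")
  w <- default_activation_profile()
  w["smoking_sitting", ] <- 0
  expect_error(generator_params(channel_activation_profile = w), "positive weight")
  expect_error(activity_protocol("reading", 400), "300 s")
  expect_error(activity_protocol(character(0), numeric(0)), "at least one")
  # 16-subject default emulation: 4 smoking sessions per subject
  expect_equal(sum(default_protocol()$activity %in% smoking_classes()), 4L)
})
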