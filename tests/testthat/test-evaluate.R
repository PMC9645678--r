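test_that("LOSO folds partition subjects correctly", {
  ids <- sprintf("S%02d", 1:16)
  folds <- loso_folds(ids)
  expect_length(folds, 16L)
  for (f in folds) {
    expect_false(f$test %in% f$train)
    expect_setequal(c(f$train, f$test), ids)
  }
  expect_setequal(vapply(folds, `[[`, "", "test"), ids)
  expect_error(loso_folds(c("A", "A", "B")), "duplicate")
  expect_error(loso_folds("A"), "at least 2")
})

test_that("confusion counts agree with an independent tally oracle", {
  expect_equal(unclass(confusion(c(1, 0, 1), c(1, 0, 1))),
               c(tp = 2L, fp = 0L, fn = 0L, tn = 1L))
  p <- c(1, 0, 1, 0); y <- 1 - p
  cm <- confusion(p, y)
  expect_equal(cm[["tp"]] + cm[["tn"]], 0L)

  set.seed(99)
  for (r in 1:25) {
    n <- 200
    pred <- rbinom(n, 1, 0.4); truth <- rbinom(n, 1, 0.3)
    cm <- confusion(pred, truth)
    # oracle: explicit loop tally
    tally <- c(tp = 0L, fp = 0L, fn = 0L, tn = 0L)
    for (i in seq_len(n)) {
      k <- if (pred[i] == 1 && truth[i] == 1) "tp" else
        if (pred[i] == 1) "fp" else if (truth[i] == 1) "fn" else "tn"
      tally[k] <- tally[k] + 1L
    }
    expect_equal(unclass(cm), tally)
    expect_equal(sum(cm), n)
  }
  expect_error(confusion(1, c(1, 0)), "length")
})

test_that("metrics match their definitions and flag degenerate cases", {
  cm <- smokescreen:::as_confusion(5091, 697, 1135, 11574)
  m <- metrics(cm)
  expect_equal(round(m[["precision"]], 2), 0.88)
  expect_equal(round(m[["recall"]], 2), 0.82)
  expect_equal(round(m[["accuracy"]], 2), 0.90)

  perfect <- metrics(smokescreen:::as_confusion(7, 0, 0, 5))
  expect_true(all(unclass(perfect) == 1))

  none_pred <- metrics(smokescreen:::as_confusion(0, 0, 3, 5))
  expect_equal(none_pred[["precision"]], 0)
  expect_true(attr(none_pred, "degenerate"))
  expect_error(metrics(smokescreen:::as_confusion(0, 0, 0, 0)), "all-zero")

  # oracle: recompute from the expanded label-pair multiset
  set.seed(3)
  for (r in 1:25) {
    counts <- rmultinom(1, 500, c(0.3, 0.2, 0.1, 0.4))[, 1]
    cm <- smokescreen:::as_confusion(counts[1], counts[2], counts[3], counts[4])
    pred <- rep(c(1, 1, 0, 0), counts)
    truth <- rep(c(1, 0, 1, 0), counts)
    expect_equal(unclass(metrics(cm)), unclass(metrics(confusion(pred, truth))))
  }
})

test_that("accumulation is an element-wise, order-invariant sum", {
  a <- smokescreen:::as_confusion(1, 2, 3, 4)
  b <- smokescreen:::as_confusion(10, 20, 30, 40)
  c_ <- smokescreen:::as_confusion(5, 5, 5, 5)
  expect_equal(unclass(accumulate(list(a))), unclass(a))
  expect_equal(unclass(accumulate(list(a, b))),
               c(tp = 11L, fp = 22L, fn = 33L, tn = 44L))
  expect_equal(unclass(accumulate(list(a, b, c_))),
               unclass(accumulate(list(c_, b, a))))
  expect_error(accumulate(list()), "no confusion")
})

test_that("exact McNemar matches the closed-form binomial tail", {
  y <- rep(c(0, 1), 50)
  same <- mcnemar_test(y, y, y)
  expect_equal(same$p_value, 1)
  expect_equal(same$b + same$c, 0L)

  # b = 10, c = 0: p = 2 * (1/2)^10
  truth <- rep(1, 20)
  a <- rep(1, 20)
  b <- c(rep(0, 10), rep(1, 10))
  mt <- mcnemar_test(a, b, truth)
  expect_equal(mt$b, 10L); expect_equal(mt$c, 0L)
  expect_equal(mt$p_value, 2 * 0.5^10, tolerance = 1e-12)

  # swapping classifiers swaps b and c, p unchanged
  mt2 <- mcnemar_test(b, a, truth)
  expect_equal(mt2$b, mt$c)
  expect_equal(mt2$c, mt$b)
  expect_equal(mt2$p_value, mt$p_value)
  expect_error(mcnemar_test(a, b[1:5], truth), "length")
})

test_that("exact and chi-square McNemar agree in the moderate-count regime", {
  set.seed(17)
  for (r in 1:30) {
    n <- sample(50:400, 1)
    b <- rbinom(1, n, 0.5); c_ <- n - b
    if (abs(b - c_) > 3 * sqrt(n)) next
    truth <- rep(1, b + c_)
    pa <- c(rep(1, b), rep(0, c_))
    pb <- 1 - pa
    pe <- mcnemar_test(pa, pb, truth, method = "exact")$p_value
    pc <- mcnemar_test(pa, pb, truth, method = "chisq")$p_value
    expect_true(pe > 0 && pe <= 1)
    expect_lt(abs(pe - pc) / pe, 0.10)
  }
})

test_that("surrogate LOSO experiment conserves windows and isolates folds", {
  cohort <- fixture_cohort()
  configs <- list(imu = imu_channels(), semg_selected = paste0("semg", c(6, 1, 7, 4, 5)))
  res <- run_experiment(cohort, configs, spec_cfg = reduced_spectrogram_config(),
                        classifier = "surrogate", seed = 3)
  n_windows_total <- sum(vapply(cohort, function(s) {
    nrow(segment(s$recording))
  }, 0))
  for (r in res) {
    expect_equal(sum(r$accumulated$confusion), n_windows_total)
    expect_length(r$folds, length(cohort))
    # accumulated = element-wise sum of folds
    expect_equal(unclass(r$accumulated$confusion),
                 unclass(accumulate(lapply(r$folds, `[[`, "confusion"))))
  }
  # paired comparisons on shared windows
  paired <- attr(res, "paired")
  expect_named(paired, "imu vs semg_selected")
})

test_that("standardization statistics never see the held-out subject", {
  cohort <- fixture_cohort()
  configs <- list(imu = imu_channels())
  res <- run_experiment(cohort, configs, spec_cfg = reduced_spectrogram_config(),
                        classifier = "surrogate", seed = 3)
  # audit: refit the standardizer from the train subjects only and compare
  specs <- lapply(cohort, smokescreen:::prepare_subject, channels = imu_channels(),
                  win_cfg = windowing_config(), spec_cfg = reduced_spectrogram_config())
  names(specs) <- names(cohort)
  for (f in res$imu$folds) {
    ref <- fit_standardizer(smokescreen:::pool_specs(specs[f$train_subjects]))
    expect_equal(f$standardizer$mean, ref$mean, tolerance = 1e-12)
    expect_equal(f$standardizer$sd, ref$sd, tolerance = 1e-12)
    # including the test subject would change the statistics
    all_st <- fit_standardizer(smokescreen:::pool_specs(specs))
    expect_false(isTRUE(all.equal(f$standardizer$mean, all_st$mean,
                                  tolerance = 1e-12)))
    expect_false(f$subject_id %in% f$train_subjects)
  }
})
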