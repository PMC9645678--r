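#' Leave-one-subject-out folds
#'
#' @param cohort List of per-subject `(recording, log)` pairs, or a character
#'   vector of subject ids.
#' @return List of folds, each `list(train = ids, test = id)`; every subject
#'   is the test subject exactly once.
#' @export
loso_folds <- function(cohort) {
  ids <- if (is.character(cohort)) cohort else {
    vapply(cohort, function(s) s$recording$subject_id, "")
  }
  ids <- unname(ids)
  if (length(ids) < 2L) stopf("LOSO needs at least 2 subjects")
  if (anyDuplicated(ids)) stopf("duplicate subject ids")
  lapply(seq_along(ids), function(i) list(train = ids[-i], test = ids[i]))
}

#' Confusion matrix of binary predictions
#'
#' @param predicted,truth Equal-length binary (0/1) vectors.
#' @return Named integer vector of class `confusion_matrix` with elements
#'   `tp`, `fp`, `fn`, `tn`; counts sum to the vector length.
#' @export
confusion <- function(predicted, truth) {
  if (length(predicted) != length(truth)) {
    stopf("prediction and truth vectors differ in length (%d vs %d)",
          length(predicted), length(truth))
  }
  if (length(predicted) == 0L) stopf("empty prediction vector")
  p <- as.integer(predicted); y <- as.integer(truth)
  structure(c(tp = sum(p == 1L & y == 1L), fp = sum(p == 1L & y == 0L),
              fn = sum(p == 0L & y == 1L), tn = sum(p == 0L & y == 0L)),
            class = "confusion_matrix")
}

as_confusion <- function(tp, fp, fn, tn) {
  structure(c(tp = as.integer(tp), fp = as.integer(fp),
              fn = as.integer(fn), tn = as.integer(tn)),
            class = "confusion_matrix")
}

#' Recall, precision, F1 and accuracy from a confusion matrix
#'
#' `precision = tp/(tp+fp)`, `recall = tp/(tp+fn)`, `f1` their harmonic mean,
#' `accuracy = (tp+tn)/total`. A zero denominator yields 0 for the affected
#' metric and sets the `degenerate` attribute.
#'
#' @param cm `confusion_matrix` (or named vector with tp/fp/fn/tn).
#' @return Named numeric vector of class `classification_metrics` with
#'   elements `recall`, `precision`, `f1`, `accuracy`.
#' @export
metrics <- function(cm) {
  tp <- as.numeric(cm[["tp"]]); fp <- as.numeric(cm[["fp"]])
  fn <- as.numeric(cm[["fn"]]); tn <- as.numeric(cm[["tn"]])
  total <- tp + fp + fn + tn
  if (total <= 0) stopf("all-zero confusion matrix: metrics undefined")
  degenerate <- FALSE
  div <- function(a, b) {
    if (b == 0) { degenerate <<- TRUE; 0 } else a / b
  }
  prec <- div(tp, tp + fp)
  rec <- div(tp, tp + fn)
  f1 <- div(2 * prec * rec, prec + rec)
  structure(c(recall = rec, precision = prec, f1 = f1,
              accuracy = (tp + tn) / total),
            class = "classification_metrics", degenerate = degenerate)
}

#' Accumulate per-fold confusion matrices
#' @param folds Non-empty list of `confusion_matrix` objects.
#' @return Their element-wise sum as a `confusion_matrix`.
#' @export
accumulate <- function(folds) {
  if (length(folds) == 0L) stopf("no confusion matrices to accumulate")
  s <- Reduce(`+`, lapply(folds, unclass))
  structure(s, class = "confusion_matrix")
}

#' McNemar paired comparison of two classifiers
#'
#' Counts the discordant windows `b` (A correct, B wrong) and `c` (A wrong,
#' B correct) over the same instances and tests symmetry. The default exact
#' test uses the two-sided binomial tail for `min(b, c)` successes in `b + c`
#' trials at rate 0.5 and is valid at any discordant count; the
#' continuity-corrected chi-square variant is available for large `b + c`.
#'
#' @param pred_a,pred_b,truth Equal-length binary vectors.
#' @param method `"exact"` or `"chisq"`.
#' @return List with `b`, `c` and `p_value`.
#' @export
mcnemar_test <- function(pred_a, pred_b, truth, method = c("exact", "chisq")) {
  method <- match.arg(method)
  if (length(pred_a) != length(truth) || length(pred_b) != length(truth)) {
    stopf("prediction vectors must match the truth vector in length")
  }
  ca <- as.integer(pred_a) == as.integer(truth)
  cb <- as.integer(pred_b) == as.integer(truth)
  b <- sum(ca & !cb)
  c_ <- sum(!ca & cb)
  n <- b + c_
  p <- if (n == 0L) {
    1
  } else if (method == "exact") {
    min(1, 2 * stats::pbinom(min(b, c_), n, 0.5))
  } else {
    stat <- (abs(b - c_) - 1)^2 / n
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
  list(b = b, c = c_, p_value = p, method = method)
}

# standard channel configurations mirroring the study's sensor combinations
#' Standard sensor-configuration channel subsets
#'
#' `semg_all`: all eight sEMG channels; `semg_selected`: the five-channel
#' subset 6, 1, 7, 4, 5; `imu`: six inertial axes; `fused`: IMU plus selected
#' sEMG channels.
#' @return Named list of channel-name vectors.
#' @export
standard_configurations <- function() {
  sel <- paste0("semg", c(6, 1, 7, 4, 5))
  list(semg_all = semg_channels(),
       semg_selected = sel,
       imu = imu_channels(),
       fused = c(imu_channels(), sel))
}

# featurize one subject at a channel union once; subsetting and
# standardization happen per fold/configuration
prepare_subject <- function(subject, channels, win_cfg, spec_cfg) {
  ws <- segment(subject$recording, win_cfg)
  ws <- label_windows(ws, subject$log, win_cfg)
  featurize(ws, subject$recording, channels, spec_cfg)
}

#' Featurize a whole cohort once for reuse across experiments
#'
#' Windows, labels and spectrogram tensors depend only on the data and the
#' windowing/spectrogram configurations, so when the same cohort is evaluated
#' under several training seeds the result of this function can be passed to
#' [run_experiment()]'s `features` argument to avoid recomputation.
#'
#' @param cohort List of per-subject `(recording, log)` pairs.
#' @param channels Channel union to featurize (default: all channels used by
#'   [standard_configurations()]).
#' @param win_cfg,spec_cfg Stage configurations.
#' @return Named list of per-subject labeled `spectrogram_set`s.
#' @export
featurize_cohort <- function(cohort,
                             channels = unique(unlist(standard_configurations())),
                             win_cfg = windowing_config(),
                             spec_cfg = reduced_spectrogram_config()) {
  specs <- lapply(cohort, prepare_subject, channels = channels,
                  win_cfg = win_cfg, spec_cfg = spec_cfg)
  names(specs) <- vapply(cohort, function(s) s$recording$subject_id, "")
  specs
}

subset_channels <- function(spec, channels) {
  i <- match(channels, spec$channels)
  if (anyNA(i)) stopf("channels not present in featurized set")
  spec$values <- spec$values[, , i, , drop = FALSE]
  spec$channels <- channels
  spec
}

# pool spectrogram sets of several subjects into one (windows stay grouped
# and ordered per subject)
pool_specs <- function(specs) {
  out <- specs[[1]]
  out$values <- array(unlist(lapply(specs, `[[`, "values"), use.names = FALSE),
                      dim = c(dim(specs[[1]]$values)[1:3],
                              sum(vapply(specs, function(s) dim(s$values)[4], 0))))
  out$windows <- do.call(rbind, lapply(specs, `[[`, "windows"))
  out$labels <- unlist(lapply(specs, `[[`, "labels"), use.names = FALSE)
  out
}

windows_of <- function(spec, win_cfg) {
  structure(spec$windows, class = c("window_set", "data.frame"),
            windowing = win_cfg)
}

#' Run the full LOSO experiment over sensor configurations
#'
#' For every configuration (a named channel subset) and every
#' leave-one-subject-out fold: per-channel standardization statistics are
#' fitted on the training subjects only, the CNN-LSTM (or a fast logistic
#' surrogate) is trained on the training subjects' window sequences, the
#' held-out subject is predicted, and the fold confusion matrix is recorded.
#' Accumulated (micro) metrics are computed from summed counts and macro
#' metrics as per-fold means; both conventions are reported. McNemar paired
#' comparisons between configurations are computed on the identical pooled
#' held-out windows.
#'
#' @param cohort List of per-subject `(recording, log)` pairs.
#' @param configurations Named list of channel subsets
#'   (default [standard_configurations()]).
#' @param win_cfg,spec_cfg,model_cfg,train_cfg Stage configurations.
#' @param seed Master seed; per-fold/config training seeds derive from it.
#' @param classifier `"cnn_lstm"` or `"surrogate"` (band-power logistic
#'   regression, used for fast wrapper evaluation and tests).
#' @param mcnemar Compute pairwise McNemar comparisons between configurations.
#' @param features Optional precomputed per-subject features from
#'   [featurize_cohort()] (must cover the union of configuration channels).
#' @param verbose Print progress.
#' @return Named list of `evaluation_result` objects (one per configuration)
#'   with attribute `paired` holding the McNemar comparisons.
#' @export
run_experiment <- function(cohort,
                           configurations = standard_configurations(),
                           win_cfg = windowing_config(),
                           spec_cfg = reduced_spectrogram_config(),
                           model_cfg = model_config(),
                           train_cfg = train_config(),
                           seed = train_cfg$seed,
                           classifier = c("cnn_lstm", "surrogate"),
                           mcnemar = TRUE, verbose = FALSE, features = NULL) {
  classifier <- match.arg(classifier)
  if (length(cohort) < 2L) stopf("experiment needs at least 2 subjects")
  if (is.null(names(configurations)) || any(names(configurations) == "")) {
    stopf("'configurations' must be a named list of channel subsets")
  }
  all_channels <- unique(unlist(configurations))
  specs <- if (is.null(features)) {
    featurize_cohort(cohort, all_channels, win_cfg, spec_cfg)
  } else features
  ids <- unname(vapply(cohort, function(s) s$recording$subject_id, ""))
  folds <- loso_folds(ids)

  results <- list()
  pred_store <- list()
  for (ci in seq_along(configurations)) {
    cname <- names(configurations)[ci]
    chans <- configurations[[ci]]
    fold_out <- list()
    preds_all <- list()
    for (fi in seq_along(folds)) {
      fold <- folds[[fi]]
      tr_spec <- pool_specs(lapply(specs[fold$train], subset_channels, channels = chans))
      te_spec <- subset_channels(specs[[fold$test]], chans)
      st <- fit_standardizer(tr_spec)
      tr_spec <- apply_standardizer(tr_spec, st)
      te_spec <- apply_standardizer(te_spec, st)
      fold_seed <- derive_seed(seed, fi, salt = ci)
      if (classifier == "cnn_lstm") {
        spec_shape <- dim(tr_spec$values)[1:3]
        net_spec <- build_model(spec_shape, model_cfg)
        tr_ws <- windows_of(tr_spec, win_cfg)
        te_ws <- windows_of(te_spec, win_cfg)
        tr_seqs <- make_sequences(tr_ws, model_cfg)
        te_seqs <- make_sequences(te_ws, model_cfg)
        tcfg <- train_cfg; tcfg$seed <- fold_seed
        model <- train_network(net_spec, flatten_tensors(tr_spec), tr_seqs, tcfg)
        pr <- predict(model, flatten_tensors(te_spec), te_seqs)
      } else {
        model <- fit_surrogate(tr_spec, seed = fold_seed)
        pr <- predict_surrogate(model, te_spec)
      }
      truth <- te_spec$labels[pr$window]
      cm <- confusion(pr$label, truth)
      fold_out[[fi]] <- list(subject_id = fold$test, confusion = cm,
                             metrics = metrics(cm),
                             standardizer = st,
                             train_subjects = fold$train, seed = fold_seed)
      preds_all[[fi]] <- data.frame(subject_id = fold$test,
                                    start_s = as.numeric(te_spec$windows$start_s[pr$window]),
                                    truth = unname(truth), prob = unname(pr$prob),
                                    pred = unname(pr$label))
      if (verbose) {
        message(sprintf("[%s] fold %d/%d (test %s): F1 %.3f", cname, fi,
                        length(folds), fold$test, metrics(cm)[["f1"]]))
      }
    }
    acc_cm <- accumulate(lapply(fold_out, `[[`, "confusion"))
    macro <- colMeans(do.call(rbind, lapply(fold_out, function(f) unclass(f$metrics))))
    results[[cname]] <- structure(
      list(configuration = cname, channels = chans, folds = fold_out,
           accumulated = list(confusion = acc_cm, micro = metrics(acc_cm),
                              macro = macro),
           predictions = do.call(rbind, preds_all), paired = NULL),
      class = "evaluation_result")
    pred_store[[cname]] <- do.call(rbind, preds_all)
  }
  if (mcnemar && length(results) > 1L) {
    nm <- names(results)
    paired <- list()
    for (i in seq_along(nm)[-length(nm)]) {
      for (j in (i + 1):length(nm)) {
        a <- pred_store[[nm[i]]]; b <- pred_store[[nm[j]]]
        mt <- mcnemar_test(a$pred, b$pred, a$truth)
        paired[[paste(nm[i], nm[j], sep = " vs ")]] <- mt
      }
    }
    attr(results, "paired") <- paired
  }
  results
}

#' @export
print.evaluation_result <- function(x, ...) {
  cm <- x$accumulated$confusion
  m <- x$accumulated$micro
  cat(sprintf("<evaluation_result> %s: %d folds\n", x$configuration, length(x$folds)))
  cat(sprintf("  accumulated TP %s FP %s FN %s TN %s\n", fmt_count(cm["tp"]),
              fmt_count(cm["fp"]), fmt_count(cm["fn"]), fmt_count(cm["tn"])))
  cat(sprintf("  micro: Rec %.3f Prec %.3f F1 %.3f Acc %.3f\n",
              m["recall"], m["precision"], m["f1"], m["accuracy"]))
  mm <- x$accumulated$macro
  cat(sprintf("  macro: Rec %.3f Prec %.3f F1 %.3f Acc %.3f\n",
              mm["recall"], mm["precision"], mm["f1"], mm["accuracy"]))
  invisible(x)
}
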