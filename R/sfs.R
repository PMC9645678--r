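# Lightweight surrogate classifier for wrapper-style channel evaluation:
# logistic regression on per-channel band-power summaries (mean and spread of
# the log-magnitude image). Orders of magnitude cheaper than the CNN-LSTM and
# sensitive to the same amplitude-modulation signal.

surrogate_features <- function(spec) {
  d <- dim(spec$values)
  v <- spec$values
  dim(v) <- c(d[1] * d[2], d[3], d[4])
  mu <- apply(v, c(3, 2), mean)
  sd_ <- apply(v, c(3, 2), stats::sd)
  x <- cbind(mu, sd_)
  colnames(x) <- c(paste0(spec$channels, "_mean"), paste0(spec$channels, "_sd"))
  x
}

#' Fit / apply the band-power logistic surrogate classifier
#'
#' @param spec Labeled, standardized `spectrogram_set` (training windows).
#' @param seed Unused randomness hook kept for interface symmetry with the
#'   network trainer.
#' @return `fit_surrogate()`: object of class `surrogate_model`.
#' @export
fit_surrogate <- function(spec, seed = 1L) {
  x <- surrogate_features(spec)
  y <- spec$labels
  if (length(unique(y)) < 2L) stopf("training set contains a single class")
  df <- data.frame(y = y, x)
  fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
  structure(list(fit = fit, channels = spec$channels), class = "surrogate_model")
}

#' @rdname fit_surrogate
#' @param model `surrogate_model` object.
#' @param threshold Decision threshold.
#' @return `predict_surrogate()`: data frame with `window`, `prob`, `label`.
#' @export
predict_surrogate <- function(model, spec, threshold = 0.5) {
  x <- as.data.frame(surrogate_features(spec))
  p <- suppressWarnings(as.numeric(stats::predict(model$fit, newdata = x,
                                                  type = "response")))
  data.frame(window = seq_len(dim(spec$values)[4]), prob = p,
             label = as.integer(p >= threshold))
}

# score one channel subset under the chosen evaluation scheme
sfs_score <- function(specs, channels, criterion, eval_scheme, seed,
                      classifier, model_cfg, train_cfg, win_cfg) {
  ids <- names(specs)
  eval_one <- function(train_ids, test_ids) {
    tr <- pool_specs(lapply(specs[train_ids], subset_channels, channels = channels))
    st <- fit_standardizer(tr)
    tr <- apply_standardizer(tr, st)
    cms <- lapply(test_ids, function(id) {
      te <- apply_standardizer(subset_channels(specs[[id]], channels), st)
      if (classifier == "surrogate") {
        mod <- fit_surrogate(tr, seed = seed)
        pr <- predict_surrogate(mod, te)
      } else {
        shape <- dim(tr$values)[1:3]
        tcfg <- train_cfg; tcfg$seed <- seed
        mod <- train_network(build_model(shape, model_cfg), flatten_tensors(tr),
                             make_sequences(windows_of(tr, win_cfg), model_cfg), tcfg)
        pr <- predict(mod, flatten_tensors(te),
                      make_sequences(windows_of(te, win_cfg), model_cfg))
      }
      confusion(pr$label, te$labels[pr$window])
    })
    accumulate(cms)
  }
  cm <- if (eval_scheme == "holdout") {
    half <- with_seed(seed, sample(ids, max(1L, length(ids) %/% 2)))
    eval_one(half, setdiff(ids, half))
  } else {
    accumulate(lapply(loso_folds(ids), function(f) eval_one(f$train, f$test)))
  }
  as.numeric(metrics(cm)[[criterion]])
}

#' Sequential forward selection of sEMG channels
#'
#' Greedy wrapper: starting from the empty subset, every step evaluates each
#' remaining candidate appended to the current subset by training and scoring
#' the classifier under the chosen evaluation scheme, and keeps the candidate
#' maximizing the criterion (ties broken toward the lowest channel index).
#' The default inner evaluation is a grouped subject-wise holdout, much
#' cheaper than running full LOSO for every candidate; full LOSO remains
#' available. The default classifier is the band-power logistic surrogate;
#' the CNN-LSTM itself can be plugged in (typically at reduced epochs).
#'
#' @param cohort List of per-subject `(recording, log)` pairs.
#' @param candidate_channels Channels to select among (default all 8 sEMG).
#' @param max_channels Number of selection steps.
#' @param criterion `"f1"` (default) or `"accuracy"`.
#' @param eval_scheme `"holdout"` (grouped subject-wise) or `"loso"`.
#' @param seed Integer seed controlling the holdout split and training.
#' @param classifier `"surrogate"` or `"cnn_lstm"`.
#' @param win_cfg,spec_cfg,model_cfg,train_cfg Stage configurations.
#' @return Object of class `sfs_trace`: data frame `(step, channel, score)`
#'   with the nested subsets as an attribute.
#' @export
sfs_select <- function(cohort, candidate_channels = semg_channels(),
                       max_channels = length(candidate_channels),
                       criterion = c("f1", "accuracy"),
                       eval_scheme = c("holdout", "loso"), seed = 1L,
                       classifier = c("surrogate", "cnn_lstm"),
                       win_cfg = windowing_config(),
                       spec_cfg = reduced_spectrogram_config(),
                       model_cfg = model_config(),
                       train_cfg = train_config(n_epochs = 2L)) {
  criterion <- match.arg(criterion)
  eval_scheme <- match.arg(eval_scheme)
  classifier <- match.arg(classifier)
  if (max_channels < 1) stopf("'max_channels' must be at least 1")
  if (max_channels > length(candidate_channels)) {
    stopf("'max_channels' exceeds the number of candidates")
  }
  if (anyDuplicated(candidate_channels)) stopf("duplicate candidate channels")
  if (length(cohort) < 2L) stopf("channel selection needs at least 2 subjects")

  # evaluate candidates in channel-index order so ties keep the lowest index
  ord <- order(match(candidate_channels, channel_names()))
  candidates <- candidate_channels[ord]
  specs <- lapply(cohort, prepare_subject, channels = candidates,
                  win_cfg = win_cfg, spec_cfg = spec_cfg)
  names(specs) <- vapply(cohort, function(s) s$recording$subject_id, "")

  current <- character(0)
  steps <- data.frame(step = integer(0), channel = character(0),
                      score = numeric(0), stringsAsFactors = FALSE)
  subsets <- list()
  for (k in seq_len(max_channels)) {
    remaining <- setdiff(candidates, current)
    scores <- vapply(remaining, function(ch) {
      sfs_score(specs, c(current, ch), criterion, eval_scheme, seed,
                classifier, model_cfg, train_cfg, win_cfg)
    }, 0)
    best <- which.max(scores)
    current <- c(current, remaining[best])
    steps <- rbind(steps, data.frame(step = k, channel = remaining[best],
                                     score = scores[best],
                                     stringsAsFactors = FALSE))
    subsets[[k]] <- current
  }
  rownames(steps) <- NULL
  structure(steps, class = c("sfs_trace", "data.frame"),
            subsets = subsets, criterion = criterion)
}

#' Best prefix subset of an SFS trace
#'
#' Returns the nested subset whose score is maximal; on ties the earliest
#' (smallest) subset wins.
#' @param trace `sfs_trace` from [sfs_select()].
#' @return Character vector of channel names, in selection order.
#' @export
best_subset <- function(trace) {
  stopifnot(inherits(trace, "sfs_trace"), nrow(trace) > 0L)
  attr(trace, "subsets")[[which.max(trace$score)]]
}

#' @export
print.sfs_trace <- function(x, ...) {
  cat(sprintf("<sfs_trace> criterion %s\n", attr(x, "criterion")))
  print(as.data.frame(x))
  invisible(x)
}

#' Write an SFS trace as delimited text (step, channel, score)
#' @param trace `sfs_trace` object.
#' @param path Output path.
#' @export
write_sfs_trace <- function(trace, path) {
  data.table::fwrite(as.data.frame(trace), path, sep = "\t")
  invisible(path)
}
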