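#' Group labeled windows into LSTM sequences
#'
#' Builds one sequence per window: the run of `sequence_length` consecutive
#' windows from the same recording that ends at that window. The sequence
#' inherits the label of its final window, so every window receives exactly
#' one prediction. Runs that would start before the recording's first window
#' are left-padded by repeating the first window and flagged as padded.
#' Sequences never mix subjects.
#'
#' @param ws Labeled `window_set` (possibly spanning several subjects).
#' @param cfg `model_config` supplying `sequence_length`.
#' @return Object of class `window_sequences`: list with `windows` (integer
#'   matrix `[n_seq, sequence_length]` of row indices into `ws`), `labels`,
#'   `padded`, `final_window`, `subject_id`.
#' @export
make_sequences <- function(ws, cfg = model_config()) {
  stopifnot(inherits(ws, "window_set"))
  L <- cfg$sequence_length
  n <- nrow(ws)
  if (n == 0L) {
    return(structure(list(windows = matrix(integer(0), 0, L),
                          labels = integer(0), padded = logical(0),
                          final_window = integer(0), subject_id = character(0)),
                     class = "window_sequences"))
  }
  rows <- seq_len(n)
  groups <- split(rows, ws$subject_id)
  mats <- list(); labs <- list(); pads <- list(); fins <- list(); subj <- list()
  for (g in groups) {
    g <- g[order(ws$start_s[g])]
    k <- seq_along(g)
    m <- matrix(0L, length(g), L)
    for (j in seq_len(L)) {
      # position j holds the window L - j windows before the end
      m[, L - j + 1L] <- g[pmax(k - j + 1L, 1L)]
    }
    mats[[length(mats) + 1L]] <- m
    labs[[length(labs) + 1L]] <- ws$label[g]
    pads[[length(pads) + 1L]] <- k < L
    fins[[length(fins) + 1L]] <- g
    subj[[length(subj) + 1L]] <- ws$subject_id[g]
  }
  structure(list(windows = do.call(rbind, mats),
                 labels = unlist(labs), padded = unlist(pads),
                 final_window = unlist(fins), subject_id = unlist(subj)),
            class = "window_sequences")
}

#' Flatten a spectrogram set into the matrix the network consumes
#'
#' Column-major (freq, time, channel) flattening, one row per window.
#' @param spec `spectrogram_set` object.
#' @return Matrix `[n_windows, F*T*C]`.
#' @export
flatten_tensors <- function(spec) {
  d <- dim(spec$values)
  m <- matrix(aperm(spec$values, c(4, 1, 2, 3)), nrow = d[4])
  m
}

bce_loss <- function(probs, y) {
  eps <- 1e-12
  -mean(y * log(probs + eps) + (1 - y) * log(1 - probs + eps))
}

# forward sequences through the full network; x is [n_windows, flat]
sequence_forward <- function(net, tables, x, seq_windows, training = FALSE,
                             dropout_mask_seed = NULL) {
  b <- nrow(seq_windows); L <- ncol(seq_windows)
  wi <- as.vector(seq_windows)
  u <- unique(wi)
  map <- match(wi, u)
  dmask <- NULL
  if (training && net$spec$config$dropout_rate > 0) {
    dmask <- matrix(stats::runif(length(u) * net$spec$config$fc_units) >=
                      net$spec$config$dropout_rate,
                    length(u), net$spec$config$fc_units) /
      (1 - net$spec$config$dropout_rate)
  }
  fwd <- cnn_forward(net, tables, x[u, , drop = FALSE], training = training,
                     dropout_mask = dmask)
  X <- fwd$features[map, , drop = FALSE]
  dim(X) <- c(b, L, ncol(fwd$features))
  lf <- lstm_forward(net, X, training = training)
  list(probs = lf$probs, cnn = fwd, lstm = lf, u = u, map = map,
       dmask = dmask, b = b, L = L)
}

mean_loss <- function(net, tables, x, seqs, batch = 256L) {
  n <- length(seqs$labels)
  tot <- 0
  for (i0 in seq(1L, n, by = batch)) {
    ii <- i0:min(n, i0 + batch - 1L)
    sf <- sequence_forward(net, tables, x, seqs$windows[ii, , drop = FALSE],
                           training = FALSE)
    tot <- tot + bce_loss(sf$probs, seqs$labels[ii]) * length(ii)
  }
  tot / n
}

#' Train the CNN-LSTM window classifier
#'
#' Runs seeded mini-batch Adam over the training sequences with binary
#' cross-entropy loss. Within one mini-batch, windows shared by several
#' sequences are forwarded through the convolutional stack once and their
#' feature gradients accumulated, which is exact and much cheaper than
#' duplicating them. Per-epoch training loss is recorded; the loss at
#' initialization is stored as epoch 0.
#'
#' @param spec `cnn_lstm_spec` from [build_model()].
#' @param x Matrix `[n_windows, F*T*C]` of flattened (standardized) window
#'   tensors; see [flatten_tensors()].
#' @param seqs `window_sequences` from [make_sequences()].
#' @param cfg `train_config` object.
#' @param verbose Print per-epoch loss.
#' @return Object of class `cnn_lstm`: the trained model with parameters,
#'   batch-norm state, training history and provenance.
#' @export
train_network <- function(spec, x, seqs, cfg = train_config(), verbose = FALSE) {
  stopifnot(inherits(spec, "cnn_lstm_spec"), inherits(cfg, "train_config"))
  y <- seqs$labels
  if (length(unique(y)) < 2L) {
    stopf("training set contains a single class; the binary problem is degenerate")
  }
  if (ncol(x) != prod(spec$input_shape)) {
    stopf("x has %d columns but the model expects %d", ncol(x), prod(spec$input_shape))
  }
  tables <- network_tables(spec)
  with_seed(cfg$seed, {
    net <- init_network(spec, seed = stats::runif(1, 1, 2^30))
    adam_m <- lapply(net$params, function(p) p * 0)
    adam_v <- adam_m
    step <- 0L
    history <- data.frame(epoch = 0L,
                          loss = mean_loss(net, tables, x, seqs))
    n_seq <- length(y)
    for (ep in seq_len(cfg$n_epochs)) {
      ord <- sample.int(n_seq)
      ep_loss <- 0
      for (i0 in seq(1L, n_seq, by = cfg$batch_size)) {
        ii <- ord[i0:min(n_seq, i0 + cfg$batch_size - 1L)]
        sw <- seqs$windows[ii, , drop = FALSE]
        yb <- y[ii]
        sf <- sequence_forward(net, tables, x, sw, training = TRUE)
        net$state <- sf$cnn$state
        ep_loss <- ep_loss + bce_loss(sf$probs, yb) * length(ii)
        # backward
        dlogit <- matrix((sf$probs - yb) / length(yb), ncol = 1)
        lb <- lstm_backward(net, sf$lstm, dlogit)
        dX <- lb$dX
        dim(dX) <- c(sf$b * sf$L, dim(dX)[3])
        rs <- rowsum(dX, sf$map)
        dfeat <- matrix(0, length(sf$u), ncol(dX))
        dfeat[as.integer(rownames(rs)), ] <- rs
        cg <- cnn_backward(net, tables, sf$cnn, dfeat, dropout_mask = sf$dmask)
        grads <- c(cg, lb$grads)
        # global gradient-norm clipping
        if (is.finite(cfg$max_grad_norm)) {
          gn <- sqrt(sum(vapply(grads, function(g) sum(g * g), 0)))
          if (gn > cfg$max_grad_norm) {
            grads <- lapply(grads, function(g) g * (cfg$max_grad_norm / gn))
          }
        }
        # Adam
        step <- step + 1L
        b1 <- 0.9; b2 <- 0.999
        for (nm in names(grads)) {
          g <- grads[[nm]]
          adam_m[[nm]] <- b1 * adam_m[[nm]] + (1 - b1) * g
          adam_v[[nm]] <- b2 * adam_v[[nm]] + (1 - b2) * g * g
          mh <- adam_m[[nm]] / (1 - b1^step)
          vh <- adam_v[[nm]] / (1 - b2^step)
          net$params[[nm]] <- net$params[[nm]] -
            cfg$learning_rate * mh / (sqrt(vh) + 1e-8)
        }
      }
      history <- rbind(history, data.frame(epoch = ep, loss = ep_loss / n_seq))
      if (verbose) message(sprintf("epoch %d: loss %.4f", ep, ep_loss / n_seq))
    }
    structure(list(spec = spec, params = net$params, state = net$state,
                   history = history,
                   provenance = list(train_config = cfg, seed = cfg$seed,
                                     n_sequences = n_seq)),
              class = "cnn_lstm")
  })
}

#' @export
print.cnn_lstm <- function(x, ...) {
  cat(sprintf("<cnn_lstm> trained on %d sequences; loss %.4f -> %.4f over %d epochs\n",
              x$provenance$n_sequences, x$history$loss[1],
              x$history$loss[nrow(x$history)], max(x$history$epoch)))
  print(x$spec)
  invisible(x)
}

#' Predict smoking probabilities for window sequences
#'
#' Deterministic inference pass (batch-norm running statistics, no dropout).
#' Each sequence yields the probability for its final window, so every window
#' of the underlying recordings receives exactly one prediction.
#'
#' @param object Trained `cnn_lstm` model.
#' @param x Matrix `[n_windows, F*T*C]` of flattened standardized tensors.
#' @param seqs `window_sequences` object.
#' @param threshold Decision threshold on the probability (default 0.5).
#' @param batch Inference batch size.
#' @param ... Unused.
#' @return Data frame with columns `window` (row index into the window set),
#'   `prob` and `label`.
#' @export
predict.cnn_lstm <- function(object, x, seqs, threshold = 0.5, batch = 256L, ...) {
  if (ncol(x) != prod(object$spec$input_shape)) {
    stopf("x has %d columns but the model expects %d",
          ncol(x), prod(object$spec$input_shape))
  }
  tables <- network_tables(object$spec)
  net <- list(spec = object$spec, params = object$params, state = object$state)
  n <- length(seqs$labels)
  probs <- numeric(n)
  for (i0 in seq(1L, n, by = batch)) {
    ii <- i0:min(n, i0 + batch - 1L)
    sf <- sequence_forward(net, tables, x, seqs$windows[ii, , drop = FALSE],
                           training = FALSE)
    probs[ii] <- sf$probs
  }
  data.frame(window = seqs$final_window, prob = probs,
             label = as.integer(probs >= threshold))
}

#' Save / load a trained model with its provenance
#' @param model `cnn_lstm` object.
#' @param path File path.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "cnn_lstm"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "cnn_lstm")) stopf("'%s' does not contain a cnn_lstm model", path)
  m
}
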