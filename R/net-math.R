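# Numerical core of the CNN-LSTM. The convolutional blocks (im2col gather,
# GEMM convolution, batch normalization, rectifier, max pooling) run in
# compiled code (src/conv.cpp) with hand-written backward passes; the LSTM
# head, whose arrays are small, is implemented here over BLAS.
#
# Layout: activations for a batch of n windows enter as [n, flat] matrices
# with column-major (freq, time, channel) flattening and are carried through
# the conv stack transposed as [flat, n].

# patch index matrix [n_pos, K]: entry (pos, k) is the linear index into the
# flattened (h, w, c) input of patch element k at output position pos;
# positions ordered column-major over (out_row, out_col), patch elements over
# (filter_row, filter_col, channel)
conv_patch_index <- function(h, w, cin, fh, fw) {
  oh <- h - fh + 1L; ow <- w - fw + 1L
  corner <- outer(seq_len(oh), (seq_len(ow) - 1L) * h, `+`)        # [oh, ow]
  offs <- outer(seq_len(fh) - 1L, (seq_len(fw) - 1L) * h, `+`)     # [fh, fw]
  offs <- outer(as.vector(offs), (seq_len(cin) - 1L) * (h * w), `+`)
  idx <- outer(as.vector(corner), as.vector(offs), `+`)            # [n_pos, K]
  storage.mode(idx) <- "integer"
  idx
}

# source position matrix [n_pool, pool^2] for max pooling; 0 marks a missing
# element of a partial edge neighborhood (ceil mode)
pool_source_index <- function(oh, ow, pool, edge) {
  ph <- pooled_dim(oh, pool, edge); pw <- pooled_dim(ow, pool, edge)
  cols <- list()
  for (dx in seq_len(pool)) {
    for (dy in seq_len(pool)) {
      ry <- (seq_len(ph) - 1L) * pool + dy
      rx <- (seq_len(pw) - 1L) * pool + dx
      src <- outer(ry, (rx - 1L) * oh, `+`)
      src[outer(ry > oh, rx > ow, `|`)] <- 0L
      cols[[length(cols) + 1L]] <- as.integer(src)
    }
  }
  do.call(cbind, cols)
}

# index tables for a spec, computed once per training run
network_tables <- function(spec) {
  geo <- spec_geometry(spec)
  conv_idx <- lapply(geo$conv, function(l) {
    conv_patch_index(l$in_shape[1], l$in_shape[2], l$in_shape[3],
                     l$filter[1], l$filter[2])
  })
  pool_idx <- lapply(geo$pool, function(l) {
    pool_source_index(l$in_shape[1], l$in_shape[2], l$pool, l$edge)
  })
  list(geo = geo, conv_idx = conv_idx, pool_idx = pool_idx)
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

conv_param <- function(p, what) {
  lapply(seq_len(3L), function(k) p[[paste0("conv", k, "_", what)]])
}

# forward pass of the convolutional feature extractor for a batch of windows;
# X is [n, flat_input]; returns fc-layer features plus the C++ session
# holding the per-block caches for backward
cnn_forward <- function(net, tables, X, training = FALSE, dropout_mask = NULL) {
  p <- net$params; st <- net$state
  n <- nrow(X)
  sess <- conv_session_new()
  fb <- conv_stack_forward_cpp(
    sess, t(X), conv_param(p, "W"), conv_param(p, "gamma"),
    conv_param(p, "beta"), tables$conv_idx, tables$pool_idx, training,
    lapply(1:3, function(k) st[[paste0("conv", k, "_rmean")]]),
    lapply(1:3, function(k) st[[paste0("conv", k, "_rvar")]]),
    BN_EPS)
  if (training) {
    for (k in 1:3) {
      st[[paste0("conv", k, "_rmean")]] <-
        (1 - BN_MOMENTUM) * st[[paste0("conv", k, "_rmean")]] +
        BN_MOMENTUM * as.numeric(fb$mus[[k]])
      st[[paste0("conv", k, "_rvar")]] <-
        (1 - BN_MOMENTUM) * st[[paste0("conv", k, "_rvar")]] +
        BN_MOMENTUM * as.numeric(fb$vars[[k]])
    }
  }
  At <- fb$At_last
  feat <- crossprod(At, p$fc_W) + rep(p$fc_b, each = n)   # [n, fc]
  if (training && !is.null(dropout_mask)) feat <- feat * dropout_mask
  list(features = feat, flat = At, sess = sess, state = st)
}

# backward through the convolutional stack; dfeat is the gradient at the
# (post-dropout) fc features. Returns parameter gradients.
cnn_backward <- function(net, tables, fwd, dfeat, dropout_mask = NULL) {
  p <- net$params
  grads <- list()
  if (!is.null(dropout_mask)) dfeat <- dfeat * dropout_mask
  grads$fc_W <- fwd$flat %*% dfeat
  grads$fc_b <- colSums(dfeat)
  dAt <- tcrossprod(p$fc_W, dfeat)   # [flat, n] in (pos, map) order
  bb <- conv_stack_backward_cpp(fwd$sess, dAt, conv_param(p, "W"),
                                conv_param(p, "gamma"), conv_param(p, "beta"),
                                tables$conv_idx)
  for (k in 1:3) {
    grads[[paste0("conv", k, "_W")]] <- bb$dWs[[k]]
    grads[[paste0("conv", k, "_gamma")]] <- as.numeric(bb$dgammas[[k]])
    grads[[paste0("conv", k, "_beta")]] <- as.numeric(bb$dbetas[[k]])
  }
  grads
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# batched LSTM stack forward over feature sequences X [n, T, input];
# returns output probabilities and per-step caches
lstm_forward <- function(net, X, training = FALSE) {
  p <- net$params
  cfg <- net$spec$config
  n <- dim(X)[1]; Tlen <- dim(X)[2]
  H <- cfg$lstm_cell_size
  layers <- list()
  inp <- X
  for (l in seq_len(cfg$n_lstm_layers)) {
    W <- p[[paste0("lstm", l, "_W")]]
    b <- p[[paste0("lstm", l, "_b")]]
    h <- matrix(0, n, H); cs <- matrix(0, n, H)
    steps <- vector("list", Tlen)
    out <- array(0, dim = c(n, Tlen, H))
    for (t in seq_len(Tlen)) {
      x_t <- inp[, t, , drop = FALSE]; dim(x_t) <- c(n, dim(inp)[3])
      h_prev <- h
      Z <- cbind(x_t, h_prev) %*% W + rep(b, each = n)
      i <- sigmoid(Z[, 1:H, drop = FALSE])
      f <- sigmoid(Z[, (H + 1):(2 * H), drop = FALSE])
      g <- tanh(Z[, (2 * H + 1):(3 * H), drop = FALSE])
      o <- sigmoid(Z[, (3 * H + 1):(4 * H), drop = FALSE])
      c_prev <- cs
      cs <- f * c_prev + i * g
      tc <- tanh(cs)
      h <- o * tc
      steps[[t]] <- list(x = x_t, h_prev = h_prev, i = i, f = f, g = g, o = o,
                         c_prev = c_prev, tc = tc)
      out[, t, ] <- h
    }
    layers[[l]] <- list(steps = steps, out = out, input = inp)
    inp <- out
  }
  h_T <- out[, Tlen, ]; dim(h_T) <- c(n, H)
  logits <- h_T %*% p$out_W + p$out_b
  probs <- sigmoid(logits)
  list(probs = as.numeric(probs), h_T = h_T, layers = layers, Tlen = Tlen)
}

# backward through the LSTM stack given dlogit [n, 1]; returns parameter
# gradients and the gradient at the input feature sequences [n, T, fc_units]
lstm_backward <- function(net, fwd, dlogit) {
  p <- net$params
  cfg <- net$spec$config
  H <- cfg$lstm_cell_size
  n <- nrow(dlogit); Tlen <- fwd$Tlen
  grads <- list()
  grads$out_W <- crossprod(fwd$h_T, dlogit)
  grads$out_b <- sum(dlogit)
  # gradient flowing into the top layer's hidden states
  dtop <- array(0, dim = c(n, Tlen, H))
  dtop[, Tlen, ] <- dlogit %*% t(p$out_W)
  dinp <- dtop
  for (l in rev(seq_len(cfg$n_lstm_layers))) {
    W <- p[[paste0("lstm", l, "_W")]]
    cache <- fwd$layers[[l]]
    in_sz <- dim(cache$input)[3]
    dW <- matrix(0, nrow(W), ncol(W)); db <- numeric(4 * H)
    dX <- array(0, dim = c(n, Tlen, in_sz))
    dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
    for (t in rev(seq_len(Tlen))) {
      s <- cache$steps[[t]]
      dh <- dh_next + dinp[, t, ]
      dc <- dc_next + dh * s$o * (1 - s$tc^2)
      do_ <- dh * s$tc
      di <- dc * s$g
      dg <- dc * s$i
      df <- dc * s$c_prev
      dc_next <- dc * s$f
      dZ <- cbind(di * s$i * (1 - s$i),
                  df * s$f * (1 - s$f),
                  dg * (1 - s$g^2),
                  do_ * s$o * (1 - s$o))
      xh <- cbind(s$x, s$h_prev)
      dW <- dW + crossprod(xh, dZ)
      db <- db + colSums(dZ)
      dxh <- tcrossprod(dZ, W)
      dX[, t, ] <- dxh[, seq_len(in_sz)]
      dh_next <- dxh[, in_sz + seq_len(H)]
    }
    grads[[paste0("lstm", l, "_W")]] <- dW
    grads[[paste0("lstm", l, "_b")]] <- db
    dinp <- dX
  }
  list(grads = grads, dX = dinp)
}
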