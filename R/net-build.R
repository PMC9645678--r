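#' CNN-LSTM model configuration
#'
#' Architecture hyper-parameters of the window classifier: three convolutional
#' blocks (convolution, batch normalization, rectifier, 2x2 max-pooling) with
#' feature-map depths 128/64/32 and filter spatial dimensions equal to half of
#' each layer's own input dimensions (floored, minimum 1), a 32-unit fully
#' connected feature layer with 0.5 dropout, and two LSTM layers of cell size
#' 64 reading sequences of consecutive-window features, closed by a single
#' sigmoid output unit.
#'
#' @param conv_feature_maps Integer triple of feature-map depths.
#' @param filter_fraction Filter size as a fraction of each conv layer's input
#'   spatial dimensions.
#' @param pool_size Max-pooling neighborhood and stride.
#' @param fc_units Width of the fully connected feature layer.
#' @param dropout_rate Dropout probability after the feature layer, in `[0, 1)`.
#' @param lstm_cell_size Hidden/cell size of each LSTM layer.
#' @param n_lstm_layers Number of stacked LSTM layers.
#' @param sequence_length Number of consecutive windows per LSTM sequence
#'   (6 windows at the default 5 s slide give about 35 s of context).
#' @param pool_edge `"ceil"` keeps a trailing partial pooling neighborhood
#'   (pooled dimension `ceiling(d / pool_size)`), so dimensions never collapse;
#'   `"floor"` drops it, in which case a dimension can collapse to zero and
#'   model construction fails with a configuration error naming the layer.
#' @return Object of class `model_config`.
#' @export
model_config <- function(conv_feature_maps = c(128L, 64L, 32L),
                         filter_fraction = 0.5, pool_size = 2L, fc_units = 32L,
                         dropout_rate = 0.5, lstm_cell_size = 64L,
                         n_lstm_layers = 2L, sequence_length = 6L,
                         pool_edge = c("ceil", "floor")) {
  pool_edge <- match.arg(pool_edge)
  if (length(conv_feature_maps) != 3L || any(conv_feature_maps < 1)) {
    stopf("'conv_feature_maps' must be three positive integers")
  }
  if (filter_fraction <= 0 || filter_fraction > 1) {
    stopf("'filter_fraction' must lie in (0, 1]")
  }
  if (dropout_rate < 0 || dropout_rate >= 1) stopf("'dropout_rate' must lie in [0, 1)")
  for (nm in c("pool_size", "fc_units", "lstm_cell_size", "n_lstm_layers",
               "sequence_length")) {
    check_positive_scalar(get(nm), nm)
  }
  structure(list(conv_feature_maps = as.integer(conv_feature_maps),
                 filter_fraction = filter_fraction,
                 pool_size = as.integer(pool_size),
                 fc_units = as.integer(fc_units),
                 dropout_rate = dropout_rate,
                 lstm_cell_size = as.integer(lstm_cell_size),
                 n_lstm_layers = as.integer(n_lstm_layers),
                 sequence_length = as.integer(sequence_length),
                 pool_edge = pool_edge),
            class = "model_config")
}

#' Training configuration
#'
#' @param optimizer Optimizer name; `"adam"` is the only implemented choice.
#' @param learning_rate Step size (default 1e-2).
#' @param batch_size Mini-batch size in sequences.
#' @param n_epochs Number of passes over the training sequences.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param loss Loss name; binary cross-entropy.
#' @param max_grad_norm Global gradient-norm clip; stabilizes the large
#'   default learning rate. `Inf` disables clipping.
#' @return Object of class `train_config`.
#' @export
train_config <- function(optimizer = "adam", learning_rate = 1e-2,
                         batch_size = 64L, n_epochs = 5L, seed = 1L,
                         loss = "bce", max_grad_norm = 5) {
  if (!identical(optimizer, "adam")) stopf("unsupported optimizer '%s'", optimizer)
  if (!identical(loss, "bce")) stopf("unsupported loss '%s'", loss)
  check_positive_scalar(learning_rate, "learning_rate")
  if (batch_size < 1) stopf("'batch_size' must be >= 1")
  if (n_epochs < 1) stopf("'n_epochs' must be >= 1")
  structure(list(optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 n_epochs = as.integer(n_epochs), seed = as.integer(seed),
                 loss = loss, max_grad_norm = max_grad_norm),
            class = "train_config")
}

pooled_dim <- function(d, pool, edge) {
  if (edge == "ceil") as.integer(ceiling(d / pool)) else as.integer(floor(d / pool))
}

#' Build the CNN-LSTM architecture description
#'
#' Walks the configured stack over a given input image shape, computing every
#' layer's filter and output dimensions. The result is a declarative
#' description (no parameters); [init_network()] instantiates seeded weights
#' for it and [model_layers()] exposes the layer enumeration for auditing.
#'
#' @param input_shape Integer triple `(freq_bins, time_bins, channels)`.
#' @param cfg `model_config` object.
#' @return Object of class `cnn_lstm_spec`.
#' @export
build_model <- function(input_shape, cfg = model_config()) {
  stopifnot(inherits(cfg, "model_config"), length(input_shape) == 3L)
  input_shape <- as.integer(input_shape)
  if (any(input_shape[1:2] < 2L)) {
    stopf("input spatial dimensions must be at least 2, got %d x %d",
          input_shape[1], input_shape[2])
  }
  layers <- list()
  h <- input_shape[1]; w <- input_shape[2]; cin <- input_shape[3]
  for (k in 1:3) {
    f <- pmax(1L, as.integer(floor(cfg$filter_fraction * c(h, w))))
    oh <- h - f[1] + 1L; ow <- w - f[2] + 1L
    maps <- cfg$conv_feature_maps[k]
    layers[[length(layers) + 1L]] <- list(
      type = "conv", block = k, in_shape = c(h, w, cin), filter = f,
      maps = maps, out_shape = c(oh, ow, maps))
    layers[[length(layers) + 1L]] <- list(type = "batch_norm", block = k, maps = maps)
    layers[[length(layers) + 1L]] <- list(type = "relu", block = k)
    ph <- pooled_dim(oh, cfg$pool_size, cfg$pool_edge)
    pw <- pooled_dim(ow, cfg$pool_size, cfg$pool_edge)
    if (ph < 1L || pw < 1L) {
      stopf("configuration error: max-pool of block %d collapses the spatial dimensions (%d x %d -> %d x %d)",
            k, oh, ow, ph, pw)
    }
    layers[[length(layers) + 1L]] <- list(
      type = "max_pool", block = k, pool = cfg$pool_size, edge = cfg$pool_edge,
      in_shape = c(oh, ow, maps), out_shape = c(ph, pw, maps))
    h <- ph; w <- pw; cin <- maps
  }
  flat <- h * w * cin
  layers[[length(layers) + 1L]] <- list(type = "flatten", units = flat)
  layers[[length(layers) + 1L]] <- list(type = "dense", units_in = flat,
                                        units = cfg$fc_units)
  layers[[length(layers) + 1L]] <- list(type = "dropout", rate = cfg$dropout_rate)
  in_sz <- cfg$fc_units
  for (l in seq_len(cfg$n_lstm_layers)) {
    layers[[length(layers) + 1L]] <- list(type = "lstm", layer = l,
                                          units_in = in_sz,
                                          cell_size = cfg$lstm_cell_size)
    in_sz <- cfg$lstm_cell_size
  }
  layers[[length(layers) + 1L]] <- list(type = "dense", units_in = in_sz,
                                        units = 1L, activation = "sigmoid")
  structure(list(input_shape = input_shape, config = cfg, layers = layers),
            class = "cnn_lstm_spec")
}

#' Enumerate the layers of a model description
#' @param spec `cnn_lstm_spec` from [build_model()].
#' @return Data frame with one row per layer: type, block, filter and output
#'   dimensions, unit counts.
#' @export
model_layers <- function(spec) {
  stopifnot(inherits(spec, "cnn_lstm_spec"))
  do.call(rbind, lapply(spec$layers, function(l) {
    data.frame(type = l$type,
               block = if (!is.null(l$block)) l$block else NA_integer_,
               filter_h = if (!is.null(l$filter)) l$filter[1] else NA_integer_,
               filter_w = if (!is.null(l$filter)) l$filter[2] else NA_integer_,
               maps = if (!is.null(l$maps)) l$maps else NA_integer_,
               units = if (!is.null(l$units)) l$units else NA_integer_,
               out_h = if (!is.null(l$out_shape)) l$out_shape[1] else NA_integer_,
               out_w = if (!is.null(l$out_shape)) l$out_shape[2] else NA_integer_,
               rate = if (!is.null(l$rate)) l$rate else NA_real_,
               cell_size = if (!is.null(l$cell_size)) l$cell_size else NA_integer_,
               activation = if (!is.null(l$activation)) l$activation else NA_character_)
  }))
}

#' @export
print.cnn_lstm_spec <- function(x, ...) {
  cat(sprintf("<cnn_lstm_spec> input %d x %d x %d\n", x$input_shape[1],
              x$input_shape[2], x$input_shape[3]))
  for (l in x$layers) {
    line <- switch(l$type,
      conv = sprintf("  conv%d: %d maps, filter %dx%d -> %dx%d", l$block,
                     l$maps, l$filter[1], l$filter[2], l$out_shape[1], l$out_shape[2]),
      batch_norm = sprintf("  batch_norm (%d maps)", l$maps),
      relu = "  relu",
      max_pool = sprintf("  max_pool %dx%d (%s) -> %dx%d", l$pool, l$pool,
                         l$edge, l$out_shape[1], l$out_shape[2]),
      flatten = sprintf("  flatten -> %d", l$units),
      dense = if (identical(l$activation, "sigmoid")) {
        sprintf("  dense %d -> %d, sigmoid output", l$units_in, l$units)
      } else sprintf("  dense %d -> %d", l$units_in, l$units),
      dropout = sprintf("  dropout %.2f", l$rate),
      lstm = sprintf("  lstm%d: cell size %d", l$layer, l$cell_size))
    cat(line, "\n")
  }
  invisible(x)
}

# spatial shapes used by the forward pass, extracted once from the spec
spec_geometry <- function(spec) {
  conv <- Filter(function(l) l$type == "conv", spec$layers)
  pool <- Filter(function(l) l$type == "max_pool", spec$layers)
  list(conv = conv, pool = pool,
       flat = Filter(function(l) l$type == "flatten", spec$layers)[[1]]$units)
}

#' Initialize seeded network parameters for a model description
#'
#' He-normal initialization for convolution and dense weights, uniform
#' Glorot-style for LSTM input/recurrent weights with forget-gate biases set
#' to 1. Batch-norm scale/shift start at 1/0 with zeroed running statistics.
#'
#' @param spec `cnn_lstm_spec` object.
#' @param seed Integer seed.
#' @return Object of class `cnn_lstm_net`: list with `spec`, flat parameter
#'   list `params`, batch-norm running state `state`, and cached geometry.
#' @export
init_network <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_lstm_spec"))
  cfg <- spec$config
  with_seed(seed, {
    params <- list(); state <- list()
    geo <- spec_geometry(spec)
    for (k in seq_along(geo$conv)) {
      l <- geo$conv[[k]]
      K <- prod(l$filter) * l$in_shape[3]
      params[[paste0("conv", k, "_W")]] <-
        matrix(stats::rnorm(K * l$maps, 0, sqrt(2 / K)), K, l$maps)
      params[[paste0("conv", k, "_gamma")]] <- rep(1, l$maps)
      params[[paste0("conv", k, "_beta")]] <- rep(0, l$maps)
      state[[paste0("conv", k, "_rmean")]] <- rep(0, l$maps)
      state[[paste0("conv", k, "_rvar")]] <- rep(1, l$maps)
    }
    params$fc_W <- matrix(stats::rnorm(geo$flat * cfg$fc_units, 0,
                                       sqrt(2 / geo$flat)), geo$flat, cfg$fc_units)
    params$fc_b <- rep(0, cfg$fc_units)
    in_sz <- cfg$fc_units; H <- cfg$lstm_cell_size
    for (l in seq_len(cfg$n_lstm_layers)) {
      r <- sqrt(6 / (in_sz + 5 * H))
      params[[paste0("lstm", l, "_W")]] <-
        matrix(stats::runif((in_sz + H) * 4 * H, -r, r), in_sz + H, 4 * H)
      b <- rep(0, 4 * H); b[(H + 1):(2 * H)] <- 1  # forget-gate bias
      params[[paste0("lstm", l, "_b")]] <- b
      in_sz <- H
    }
    params$out_W <- matrix(stats::rnorm(H, 0, 0.1), H, 1)
    params$out_b <- 0
    structure(list(spec = spec, params = params, state = state),
              class = "cnn_lstm_net")
  })
}
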