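test_that("the default architecture enumerates the published stack exactly", {
  spec <- build_model(c(256, 112, 8), model_config())
  ly <- model_layers(spec)

  conv <- ly[ly$type == "conv", ]
  expect_equal(nrow(conv), 3L)
  expect_equal(conv$maps, c(128L, 64L, 32L))
  # first-layer filter = floor(0.5 * (256, 112))
  expect_equal(c(conv$filter_h[1], conv$filter_w[1]), c(128L, 56L))
  expect_equal(sum(ly$type == "batch_norm"), 3L)
  expect_equal(sum(ly$type == "relu"), 3L)
  pools <- ly[ly$type == "max_pool", ]
  expect_equal(nrow(pools), 3L)

  dense <- ly[ly$type == "dense", ]
  expect_equal(dense$units, c(32L, 1L))          # FC(32) then sigmoid output
  expect_equal(dense$activation[2], "sigmoid")
  expect_equal(ly$rate[ly$type == "dropout"], 0.5)
  lstm <- ly[ly$type == "lstm", ]
  expect_equal(nrow(lstm), 2L)
  expect_equal(lstm$cell_size, c(64L, 64L))

  # a second build is structurally identical
  expect_identical(spec$layers, build_model(c(256, 112, 8), model_config())$layers)
})

test_that("conv filter sizing follows each layer's own input dimensions", {
  spec <- build_model(c(8, 8, 11), model_config())
  conv <- model_layers(spec)
  conv <- conv[conv$type == "conv", ]
  expect_equal(c(conv$filter_h[1], conv$filter_w[1]), c(4L, 4L))
  expect_true(all(conv$filter_h >= 1 & conv$filter_w >= 1))
})

test_that("floor-edge pooling reports a collapsing configuration by layer", {
  cfg <- model_config(pool_edge = "floor")
  expect_error(build_model(c(8, 8, 2), cfg), "block")
  expect_error(build_model(c(2, 300, 2), model_config()), NA)
  expect_error(build_model(c(1, 300, 2), model_config()), "at least 2")
})

test_that("configuration invariants are enforced", {
  expect_error(train_config(n_epochs = 0), ">= 1")
  expect_error(train_config(learning_rate = 0), "positive")
  expect_error(model_config(dropout_rate = 1), "0, 1")
  expect_error(model_config(conv_feature_maps = c(8, 8)), "three")
})

test_that("sequences are per-subject runs ending at each window", {
  s <- fixture_subject()
  ws <- label_windows(segment(s$recording), s$log)[1:11, ]
  ws <- structure(ws, class = c("window_set", "data.frame"))
  seqs <- make_sequences(ws, model_config(sequence_length = 6L))
  expect_equal(nrow(seqs$windows), 11L)
  expect_equal(sum(seqs$padded), 5L)
  expect_equal(seqs$windows[11, ], 6:11)
  expect_equal(seqs$windows[1, ], rep(1L, 6))
  expect_equal(seqs$labels, ws$label)

  # sequence_length 1: identity
  s1 <- make_sequences(ws, model_config(sequence_length = 1L))
  expect_equal(as.vector(s1$windows), seq_len(11L))

  # two subjects never mix
  ws2 <- ws; ws2$subject_id <- "S02"
  both <- bind_windows(ws, ws2)
  sq <- make_sequences(both, model_config(sequence_length = 4L))
  for (i in seq_len(nrow(sq$windows))) {
    expect_length(unique(both$subject_id[sq$windows[i, ]]), 1L)
  }
})

test_that("training rejects degenerate inputs and learns a separable set", {
  f <- fixture_features()
  mc <- model_config()
  spec <- build_model(dim(f$fs$values)[1:3], mc)
  seqs <- make_sequences(f$ws, mc)

  ones <- seqs; ones$labels <- rep(1L, length(ones$labels))
  expect_error(train_network(spec, f$x, ones, train_config()), "single class")

  # the small fixture yields only ~2 mini-batches per epoch, so give the
  # optimizer a few more passes than the study-scale default
  m <- train_network(spec, f$x, seqs, train_config(seed = 9, n_epochs = 8))
  # loss after training below loss at initialization
  expect_lt(m$history$loss[nrow(m$history)], m$history$loss[1])
  pr <- predict(m, f$x, seqs)
  acc <- mean(pr$label == f$ws$label[pr$window])
  expect_gt(acc, 0.95)
})

test_that("seeded training is reproducible and prediction is deterministic", {
  f <- fixture_features()
  mc <- model_config()
  spec <- build_model(dim(f$fs$values)[1:3], mc)
  seqs <- make_sequences(f$ws, mc)
  cfg <- train_config(seed = 21, n_epochs = 2)
  m1 <- train_network(spec, f$x, seqs, cfg)
  m2 <- train_network(spec, f$x, seqs, cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$history, m2$history)

  pr <- predict(m1, f$x, seqs)
  expect_true(all(pr$prob >= 0 & pr$prob <= 1))
  expect_identical(pr$label, as.integer(pr$prob >= 0.5))
  expect_identical(pr, predict(m1, f$x, seqs))
})

test_that("permuting sequence order permutes predictions identically", {
  f <- fixture_features()
  mc <- model_config()
  spec <- build_model(dim(f$fs$values)[1:3], mc)
  seqs <- make_sequences(f$ws, mc)
  m <- train_network(spec, f$x, seqs, train_config(seed = 4, n_epochs = 1))
  perm <- sample(length(seqs$labels))
  seqs_p <- seqs
  seqs_p$windows <- seqs$windows[perm, ]
  seqs_p$labels <- seqs$labels[perm]
  seqs_p$final_window <- seqs$final_window[perm]
  a <- predict(m, f$x, seqs)
  b <- predict(m, f$x, seqs_p)
  expect_equal(b$prob, a$prob[perm], tolerance = 1e-12)
})

test_that("analytic gradients match central finite differences", {
  # small network, full pipeline: conv stack + fc + lstm + sigmoid/BCE
  set.seed(77)
  n_win <- 12
  input_shape <- c(6, 5, 2)
  mc <- model_config(sequence_length = 3L, dropout_rate = 0)
  spec <- build_model(input_shape, mc)
  x <- matrix(rnorm(n_win * prod(input_shape)), n_win)
  seqw <- t(vapply(3:n_win, function(k) c(k - 2L, k - 1L, k), integer(3)))
  y <- rep_len(c(0, 1), nrow(seqw))
  tables <- smokescreen:::network_tables(spec)
  net <- init_network(spec, seed = 5)

  loss_fn <- function(params) {
    net2 <- net; net2$params <- params
    sf <- smokescreen:::sequence_forward(net2, tables, x, seqw, training = TRUE)
    smokescreen:::bce_loss(sf$probs, y)
  }
  # analytic gradients via the training-step backward composition
  sf <- smokescreen:::sequence_forward(net, tables, x, seqw, training = TRUE)
  dlogit <- matrix((sf$probs - y) / length(y), ncol = 1)
  lb <- smokescreen:::lstm_backward(net, sf$lstm, dlogit)
  dX <- lb$dX; dim(dX) <- c(nrow(seqw) * 3L, dim(dX)[3])
  rs <- rowsum(dX, sf$map)
  dfeat <- matrix(0, length(sf$u), ncol(dX))
  dfeat[as.integer(rownames(rs)), ] <- rs
  cg <- smokescreen:::cnn_backward(net, tables, sf$cnn, dfeat)
  grads <- c(cg, lb$grads)

  eps <- 1e-6
  for (nm in c("conv1_W", "conv2_gamma", "conv3_beta", "fc_W", "fc_b",
               "lstm1_W", "lstm2_b", "out_W", "out_b")) {
    g <- grads[[nm]]
    idx <- sample(length(g), min(4, length(g)))
    for (i in idx) {
      p_plus <- net$params; p_plus[[nm]][i] <- p_plus[[nm]][i] + eps
      p_minus <- net$params; p_minus[[nm]][i] <- p_minus[[nm]][i] - eps
      fd <- (loss_fn(p_plus) - loss_fn(p_minus)) / (2 * eps)
      expect_equal(as.numeric(g[i]), fd, tolerance = 1e-4,
                   label = sprintf("grad %s[%d]", nm, i))
    }
  }
})

test_that("models survive a save/load round trip", {
  f <- fixture_features()
  mc <- model_config()
  spec <- build_model(dim(f$fs$values)[1:3], mc)
  seqs <- make_sequences(f$ws, mc)
  m <- train_network(spec, f$x, seqs, train_config(seed = 2, n_epochs = 1))
  path <- tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(predict(m2, f$x, seqs), predict(m, f$x, seqs))
})
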