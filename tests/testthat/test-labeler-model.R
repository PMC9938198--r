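test_that("configs validate their fields", {
  expect_error(model_config(K = 4), "odd")
  expect_error(model_config(dropout = 1), "dropout")
  expect_error(train_config(patience = 0), "patience")
  expect_error(predict_labels(c(0.5), threshold = 1.5), "threshold")
})

test_that("output is a per-position softmax over two classes", {
  m <- tiny_labeler(L = 15)
  ws <- make_windows(random_rna_sequence(25), L = 15, step = 15)
  fw <- rnafrag:::nn_forward(m$params, m$buffers, m$config,
                             encode_onehot(ws), window_masks(ws) * 1L)
  sums <- apply(fw$probs, c(1, 2), sum)
  expect_equal(as.vector(sums), rep(1, length(sums)), tolerance = 1e-12)
  expect_true(all(fw$probs >= 0 & fw$probs <= 1))
})

test_that("predictions are invariant to the content of padded positions", {
  m <- tiny_labeler(L = 20, seed = 7)
  ws <- make_windows("ACGUACGUACGU", L = 20, step = 20)
  base <- predict_window_probs(m, ws)
  x <- encode_onehot(ws)
  mask <- window_masks(ws) * 1L
  # overwrite padding with every possible symbol
  for (ch in 1:5) {
    x2 <- x
    x2[1, 13:20, ] <- 0
    x2[1, 13:20, ch] <- 1
    p2 <- rnafrag:::forward_in_chunks(m$params, m$buffers, m$config, x2, mask)
    expect_equal(p2[1, 1:12], base[1, 1:12], tolerance = 1e-14)
  }
})

test_that("parameter count follows the closed form in (K, C, U, N)", {
  count_formula <- function(K, C, U, N) {
    conv <- (K * 5 * C + C) + 3 * (K * C * C + C)
    lstm <- 2 * ((C + U) * 4 * U + 4 * U)
    bn1 <- 2 * (2 * U)
    res <- (2 * U * N + N) + (N * N + N) + 2 * (N * N + N)
    bn2 <- 2 * N
    out <- N * 2 + 2
    conv + lstm + bn1 + res + bn2 + out
  }
  for (cfg in list(c(3, 8, 4, 16), c(5, 32, 32, 64), c(7, 12, 6, 10))) {
    m <- build_labeler(model_config(cfg[1], cfg[2], cfg[3], cfg[4], L = 30))
    expect_equal(n_parameters(m),
                 count_formula(cfg[1], cfg[2], cfg[3], cfg[4]))
  }
})

test_that("analytic gradients match finite differences", {
  cfg <- model_config(K = 3, C = 4, U = 3, N = 5, L = 8, dropout = 0)
  params <- rnafrag:::withr_seed(1, rnafrag:::nn_init_params(cfg))
  # nudge parameters off exact relu kinks (zero biases + sparse inputs put
  # many pre-activations at exactly 0, where the subgradient is one-sided)
  params <- rnafrag:::withr_seed(2, lapply(params, function(p) {
    p + stats::runif(length(p), 0.01, 0.02)
  }))
  buffers <- rnafrag:::nn_init_buffers(cfg)
  set.seed(11)
  B <- 3
  X <- array(0, c(B, 8, 5))
  for (b in 1:B) for (l in 1:8) X[b, l, sample(5, 1)] <- 1
  mask <- matrix(1, B, 8); mask[2, 7:8] <- 0
  y <- matrix(rbinom(B * 8, 1, 0.4), B, 8)
  loss_at <- function(p) {
    fw <- rnafrag:::nn_forward(p, buffers, cfg, X, mask, training = TRUE,
                               want_cache = TRUE)
    rnafrag:::nn_backward(p, cfg, y, fw$cache)$loss
  }
  fw <- rnafrag:::nn_forward(params, buffers, cfg, X, mask, training = TRUE,
                             want_cache = TRUE)
  bw <- rnafrag:::nn_backward(params, cfg, y, fw$cache)
  eps <- 1e-5
  for (nm in names(params)) {
    idx <- sample(length(params[[nm]]), min(4, length(params[[nm]])))
    for (i in idx) {
      p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps
      p3 <- params; p3[[nm]][i] <- p3[[nm]][i] - eps
      num <- (loss_at(p2) - loss_at(p3)) / (2 * eps)
      ana <- bw$grads[[nm]][i]
      expect_lt(abs(num - ana) / max(1e-6, abs(num) + abs(ana)), 1e-3)
    }
  }
})

test_that("the loss ignores fully masked windows", {
  cfg <- model_config(K = 3, C = 4, U = 3, N = 5, L = 8, dropout = 0)
  m <- build_labeler(cfg, seed = 1)
  x <- array(0, c(2, 8, 5)); x[, , 5] <- 1
  y <- matrix(1L, 2, 8)
  mask_half <- rbind(rep(1, 8), rep(0, 8))
  fw <- rnafrag:::nn_forward(m$params, m$buffers, cfg, x, mask_half,
                             training = TRUE, want_cache = TRUE)
  loss_half <- rnafrag:::nn_backward(m$params, cfg, y, fw$cache)$loss
  fw1 <- rnafrag:::nn_forward(m$params, m$buffers, cfg,
                              x[1, , , drop = FALSE],
                              mask_half[1, , drop = FALSE],
                              training = TRUE, want_cache = TRUE)
  loss_one <- rnafrag:::nn_backward(m$params, cfg,
                                    y[1, , drop = FALSE], fw1$cache)$loss
  expect_equal(loss_half, loss_one, tolerance = 1e-12)
})

test_that("early stopping halts after patience epochs without improvement", {
  g <- generate_structure(synth_params(), seed = 2)
  ws <- make_windows(g$structure$sequence, L = 30, step = 30)
  bl <- build_labels(g$structure, ws)
  ds <- window_dataset(encode_onehot(ws), bl$labels, bl$mask)
  m <- tiny_labeler(L = 30)
  # zero learning rate freezes the model, so the validation metric is
  # constant: first epoch registers it, second exhausts patience = 1
  tr <- train_labeler(m, ds, ds,
                      train_config(patience = 1, max_epochs = 50,
                                   batch_size = 4, learning_rate = 0,
                                   seed = 1))
  expect_equal(nrow(tr$history), 2L)
  expect_error(train_labeler(m, window_dataset(ds$x[0, , , drop = FALSE],
                                               ds$y[0, , drop = FALSE],
                                               ds$mask[0, , drop = FALSE]),
                             ds, train_config()), "empty")
})

test_that("trans-training continues from stage-1 weights", {
  small <- generate_dataset(30, synth_params(label_noise = 0.2),
                            L = 40, step = 40, seed = 3)
  tc <- train_config(patience = 1, max_epochs = 2, batch_size = 16, seed = 1)
  m <- tiny_labeler(L = 40)
  tt <- transfer_train(m, small$coarse$train, small$coarse$val,
                       small$accurate$train, small$accurate$val, tc)
  expect_true(all(c("pre-training", "trans-training") %in% tt$history$stage))
  # weights changed between stages
  expect_false(identical(tt$params, tt$pretrained$params))
  # empty accurate set degenerates to pre-training only
  empty <- rnafrag:::subset_window_dataset(small$accurate$train, integer(0))
  tt2 <- transfer_train(m, small$coarse$train, small$coarse$val,
                        empty, small$accurate$val, tc)
  expect_equal(unique(tt2$history$stage), "pre-training")
  expect_null(tt2$pretrained)
})

test_that("hyper-parameter search returns a ranked, reproducible table", {
  small <- generate_dataset(20, synth_params(), L = 30, step = 30, seed = 5)
  tc <- train_config(patience = 1, max_epochs = 1, batch_size = 16, seed = 1)
  space <- list(K = c(3, 5), C = c(4, 8), U = c(3, 6), N = c(4, 8))
  one <- tune_hyperparameters(space, budget = 1, small$accurate$train,
                              small$accurate$val, tc, L = 30, seed = 2)
  expect_equal(nrow(one), 1L)

  five <- tune_hyperparameters(space, budget = 5, small$accurate$train,
                               small$accurate$val, tc, L = 30, seed = 2)
  expect_equal(nrow(five), 5L)
  expect_true(all(diff(five$val_mcc) <= 1e-12))
  five_again <- tune_hyperparameters(space, budget = 5, small$accurate$train,
                                     small$accurate$val, tc, L = 30, seed = 2)
  expect_equal(five[c("K", "C", "U", "N", "val_mcc")],
               five_again[c("K", "C", "U", "N", "val_mcc")])
})

test_that("ensembles average member probabilities", {
  ws <- make_windows(random_rna_sequence(35), L = 20, step = 20)
  m1 <- tiny_labeler(L = 20, seed = 1)
  m2 <- tiny_labeler(L = 20, seed = 2)
  p1 <- predict_window_probs(m1, ws)
  p2 <- predict_window_probs(m2, ws)
  ens <- labeler_ensemble(list(m1, m2))
  pe <- predict_window_probs(ens, ws)
  expect_equal(pe, (p1 + p2) / 2, tolerance = 1e-12)
  # single-member ensemble is that member
  expect_equal(predict_window_probs(labeler_ensemble(list(m1)), ws), p1)
  # bounded by member min/max
  expect_true(all(pe >= pmin(p1, p2) - 1e-12 & pe <= pmax(p1, p2) + 1e-12))
  # mismatched window lengths refuse to ensemble
  expect_error(labeler_ensemble(list(m1, tiny_labeler(L = 30))),
               "mismatched")
})

test_that("label binarization follows the documented tie rule", {
  expect_equal(predict_labels(c(0, 0, 0)), c(0L, 0L, 0L))
  expect_equal(predict_labels(c(0.5, 0.49)), c(1L, 0L))
  expect_equal(predict_labels(c(0.1, 0.9), threshold = 0), c(1L, 1L))
  expect_error(predict_labels(c(-0.1)), "\\[0, 1\\]")
})

test_that("checkpoints round-trip through plain text", {
  dir <- withr::local_tempdir()
  m <- tiny_labeler(L = 20, seed = 3)
  ws <- make_windows(random_rna_sequence(20), L = 20, step = 20)
  before <- predict_window_probs(m, ws)
  save_labeler(m, file.path(dir, "ckpt"))
  m2 <- load_labeler(file.path(dir, "ckpt"))
  expect_equal(predict_window_probs(m2, ws), before, tolerance = 1e-12)
  expect_equal(glance(m2)$n_parameters, n_parameters(m))
})

test_that("tidy and glance summarise trained labelers", {
  small <- generate_dataset(20, synth_params(), L = 30, step = 30, seed = 6)
  m <- train_labeler(tiny_labeler(L = 30), small$accurate$train,
                     small$accurate$val,
                     train_config(patience = 1, max_epochs = 2,
                                  batch_size = 16, seed = 1))
  h <- tidy(m)
  expect_true(all(c("epoch", "train_loss", "val_mcc") %in% names(h)))
  g <- glance(m)
  expect_equal(g$epochs, nrow(h))
  expect_error(tidy(tiny_labeler()), "history")
})

test_that("the network learns a linearly separable toy task to near-perfect MCC", {
  # exterior := runs of A; everything else C/G/U. Guards the block stack
  # against wiring bugs: any working configuration must ace this.
  set.seed(77)
  make_toy <- function(n) {
    sets <- lapply(seq_len(n), function(k) {
      lab <- integer(0); chars <- character(0)
      while (length(lab) < 60) {
        len <- sample(3:12, 1)
        if (stats::runif(1) < 0.5) {
          chars <- c(chars, rep("A", len)); lab <- c(lab, rep(1L, len))
        } else {
          chars <- c(chars, sample(c("C", "G", "U"), len, TRUE))
          lab <- c(lab, rep(0L, len))
        }
      }
      ws <- make_windows(paste(chars[1:60], collapse = ""), L = 60, step = 60)
      bl <- build_labels(lab[1:60], ws)
      window_dataset(encode_onehot(ws), bl$labels, bl$mask)
    })
    bind_window_datasets(sets)
  }
  tr <- make_toy(120); va <- make_toy(30)
  m <- build_labeler(model_config(K = 5, C = 16, U = 8, N = 16, L = 60),
                     seed = 1)
  m <- train_labeler(m, tr, va,
                     train_config(patience = 5, max_epochs = 20,
                                  batch_size = 32, seed = 1))
  expect_gte(m$val_metric, 0.95)
})
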