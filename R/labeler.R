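#' Labeler architecture configuration
#'
#' Hyper-parameters of the exterior-loop labeler: a stack of four 1D
#' convolutions (kernel `K`, `C` channels, relu), one bidirectional LSTM
#' (`U` units per direction, tanh), batch normalization, two residual
#' fully-connected layers of width `N` (each two FC layers whose outputs are
#' joined by a shortcut), batch normalization, and a per-position two-node
#' softmax output. Dropout (default rate 0.1) acts inside the conv, LSTM and
#' residual blocks; padding positions are masked out of every layer's
#' effective input and of the loss.
#'
#' @param K Convolution kernel size (odd).
#' @param C Convolution channels.
#' @param U LSTM units per direction.
#' @param N Width of the residual fully-connected layers.
#' @param L Window length the model operates on.
#' @param dropout Dropout rate in `[0, 1)`.
#' @return A list of class `model_config`.
#' @export
model_config <- function(K = 5L, C = 32L, U = 32L, N = 64L, L = 200L,
                         dropout = 0.1) {
  K <- as.integer(K); C <- as.integer(C); U <- as.integer(U)
  N <- as.integer(N); L <- as.integer(L)
  stopifnot(K >= 1L, C >= 1L, U >= 1L, N >= 1L, L >= 1L,
            dropout >= 0, dropout < 1)
  if (K %% 2L != 1L) stop("`K` must be odd so convolutions stay centered",
                          call. = FALSE)
  structure(list(K = K, C = C, U = U, N = N, L = L, dropout = dropout),
            class = "model_config")
}

#' Training configuration
#'
#' @param patience Early-stopping patience in epochs (default 10): training
#'   stops when the validation metric has not improved for `patience`
#'   consecutive epochs, and the best-epoch weights are restored.
#' @param max_epochs Hard epoch cap.
#' @param batch_size Minibatch size.
#' @param learning_rate Initial Adam learning rate.
#' @param lr_factor Reduce-on-plateau factor: after `lr_patience` epochs
#'   without validation improvement the learning rate is multiplied by this
#'   (1 disables the schedule).
#' @param lr_patience Epochs without improvement before the rate drops.
#' @param seed Integer seed controlling initial shuffling and dropout.
#' @return A list of class `train_config`.
#' @export
train_config <- function(patience = 10L, max_epochs = 100L, batch_size = 64L,
                         learning_rate = 1e-3, lr_factor = 0.5,
                         lr_patience = 2L, seed = 1L) {
  patience <- as.integer(patience)
  stopifnot(patience >= 1L, max_epochs >= 1L, batch_size >= 1L,
            learning_rate >= 0, lr_factor > 0, lr_factor <= 1,
            lr_patience >= 1L)
  structure(list(patience = patience, max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, lr_factor = lr_factor,
                 lr_patience = as.integer(lr_patience),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build an untrained labeler
#'
#' Instantiates the network of [model_config()] with seeded Glorot-uniform
#' weights (LSTM forget-gate biases start at 1).
#'
#' @param config A [model_config()].
#' @param seed Integer seed for weight initialisation.
#' @return An object of class `rna_labeler`.
#' @export
build_labeler <- function(config = model_config(), seed = 1L) {
  stopifnot(inherits(config, "model_config"))
  params <- withr_seed(seed, nn_init_params(config))
  structure(
    list(config = config, params = params,
         buffers = nn_init_buffers(config),
         trained = FALSE, history = NULL, init_seed = as.integer(seed)),
    class = "rna_labeler"
  )
}

#' @export
print.rna_labeler <- function(x, ...) {
  cf <- x$config
  cat("Exterior-loop labeler (K=", cf$K, ", C=", cf$C, ", U=", cf$U,
      ", N=", cf$N, ", L=", cf$L, "); ", n_parameters(x), " parameters; ",
      if (x$trained) "trained" else "untrained", "\n", sep = "")
  invisible(x)
}

#' Number of trainable parameters
#'
#' @param x An `rna_labeler`.
#' @return Integer count over all weights and biases.
#' @export
n_parameters <- function(x) {
  stopifnot(inherits(x, "rna_labeler"))
  sum(vapply(x$params, length, integer(1)))
}

#' Train a labeler with early stopping
#'
#' Minimises masked cross-entropy with Adam. After each epoch the base-level
#' MCC on the validation set (threshold 0.5, evaluation mode) is recorded
#' (an undefined MCC is monitored as 0); when the monitored score fails to
#' improve for `patience` consecutive epochs training stops and the
#' best-epoch weights are restored.
#'
#' @param labeler An `rna_labeler` (trained or not; training continues from
#'   its current weights, which is what the trans-training stage relies on).
#' @param train,val `rna_window_dataset` objects whose window length matches
#'   the labeler's `L`.
#' @param tc A [train_config()].
#' @param verbose Print one line per epoch.
#' @return The trained `rna_labeler`, with a `history` tibble (epoch,
#'   train_loss, val_mcc, improved) and `val_metric` (best validation MCC).
#' @export
train_labeler <- function(labeler, train, val, tc = train_config(),
                          verbose = FALSE) {
  stopifnot(inherits(labeler, "rna_labeler"),
            inherits(train, "rna_window_dataset"),
            inherits(val, "rna_window_dataset"),
            inherits(tc, "train_config"))
  n_win <- dim(train$x)[[1L]]
  if (n_win == 0L || dim(val$x)[[1L]] == 0L) {
    stop("empty training or validation dataset", call. = FALSE)
  }
  if (dim(train$x)[[2L]] != labeler$config$L) {
    stop("dataset window length ", dim(train$x)[[2L]],
         " does not match model L = ", labeler$config$L, call. = FALSE)
  }
  cfg <- labeler$config
  params <- labeler$params
  buffers <- labeler$buffers
  opt <- adam_init(params)
  lr <- tc$learning_rate
  best <- -Inf
  best_params <- params
  best_buffers <- buffers
  wait <- 0L
  lr_wait <- 0L
  history <- vector("list", tc$max_epochs)
  withr_seed(tc$seed, {
    for (epoch in seq_len(tc$max_epochs)) {
      idx <- sample.int(n_win)
      losses <- numeric(0)
      for (start in seq(1L, n_win, by = tc$batch_size)) {
        bidx <- idx[start:min(start + tc$batch_size - 1L, n_win)]
        xb <- train$x[bidx, , , drop = FALSE]
        yb <- train$y[bidx, , drop = FALSE]
        mb <- train$mask[bidx, , drop = FALSE]
        if (sum(mb) == 0) next # fully padded batch contributes no loss
        fw <- nn_forward(params, buffers, cfg, xb, mb, training = TRUE,
                         want_cache = TRUE)
        buffers <- fw$buffers
        bw <- nn_backward(params, cfg, yb, fw$cache)
        losses <- c(losses, bw$loss)
        upd <- adam_step(params, bw$grads, opt, lr)
        params <- upd$params
        opt <- upd$state
      }
      val_mcc <- eval_mcc(params, buffers, cfg, val)
      # a degenerate epoch (no positive predictions or truths) has an
      # undefined MCC; monitor it as 0 so early stopping stays well-defined
      score <- if (is.na(val_mcc)) 0 else val_mcc
      improved <- score > best + 1e-9
      if (improved) {
        best <- score
        best_params <- params
        best_buffers <- buffers
        wait <- 0L
        lr_wait <- 0L
      } else {
        wait <- wait + 1L
        lr_wait <- lr_wait + 1L
        if (tc$lr_factor < 1 && lr_wait >= tc$lr_patience && lr > 0) {
          lr <- max(lr * tc$lr_factor, 1e-5)
          lr_wait <- 0L
        }
      }
      history[[epoch]] <- tibble::tibble(
        epoch = epoch, train_loss = mean(losses), val_mcc = val_mcc,
        lr = lr, improved = improved
      )
      if (verbose) {
        cat(sprintf("epoch %3d  loss %.4f  val MCC %s%s\n", epoch,
                    mean(losses),
                    ifelse(is.na(val_mcc), "NA", sprintf("%.4f", val_mcc)),
                    if (improved) " *" else ""))
      }
      if (wait >= tc$patience) break
    }
  })
  labeler$params <- best_params
  labeler$buffers <- best_buffers
  labeler$trained <- TRUE
  labeler$val_metric <- best
  labeler$history <- dplyr::bind_rows(history)
  labeler$train_config <- tc
  labeler
}

# validation base-level MCC in evaluation mode (threshold 0.5)
eval_mcc <- function(params, buffers, cfg, ds, chunk = 256L) {
  probs <- forward_in_chunks(params, buffers, cfg, ds$x, ds$mask, chunk)
  pred <- (probs >= 0.5) * 1L
  cm <- base_confusion(as.vector(pred), as.vector(ds$y),
                       as.vector(ds$mask))
  compute_metrics(cm)$MCC
}

forward_in_chunks <- function(params, buffers, cfg, x, mask, chunk = 256L) {
  n <- dim(x)[[1L]]
  out <- matrix(NA_real_, n, dim(x)[[2L]])
  for (start in seq(1L, n, by = chunk)) {
    idx <- start:min(start + chunk - 1L, n)
    fw <- nn_forward(params, buffers, cfg, x[idx, , , drop = FALSE],
                     mask[idx, , drop = FALSE], training = FALSE)
    out[idx, ] <- fw$probs[, , 2L]
  }
  out
}

#' Two-stage training on coarse then accurate labels
#'
#' Stage 1 (pre-training) fits the labeler on the large coarse-label
#' datasets; stage 2 (trans-training) continues from the stage-1 weights on
#' the accurate datasets with identical hyper-parameters — no layer
#' freezing, no learning-rate drop — both stages early-stopped. With an
#' empty accurate set the result degenerates to pre-training only.
#'
#' @param labeler An `rna_labeler`.
#' @param coarse_train,coarse_val Coarse-label `rna_window_dataset`s.
#' @param accurate_train,accurate_val Accurate-label datasets (may be `NULL`
#'   or empty to skip stage 2).
#' @param tc A [train_config()] used unchanged in both stages.
#' @param verbose Print per-epoch lines.
#' @return The trained `rna_labeler`; `$pretrained` holds the stage-1 model
#'   and `$history` gains a `stage` column.
#' @export
transfer_train <- function(labeler, coarse_train, coarse_val,
                           accurate_train, accurate_val,
                           tc = train_config(), verbose = FALSE) {
  stage1 <- train_labeler(labeler, coarse_train, coarse_val, tc,
                          verbose = verbose)
  stage1$history$stage <- "pre-training"
  empty_acc <- is.null(accurate_train) ||
    dim(accurate_train$x)[[1L]] == 0L
  if (empty_acc) {
    stage1$pretrained <- NULL
    return(stage1)
  }
  stage2 <- train_labeler(stage1, accurate_train, accurate_val, tc,
                          verbose = verbose)
  stage2$history$stage <- "trans-training"
  stage2$history <- dplyr::bind_rows(stage1$history, stage2$history)
  stage2$pretrained <- stage1
  stage2
}

#' Sequential model-based hyper-parameter search
#'
#' Searches the (K, C, U, N) box with a surrogate-guided strategy: an
#' initial batch of random configurations, then, for each remaining trial,
#' a random-forest surrogate fitted to the observed (config, validation
#' MCC) pairs proposes the candidate maximising an upper-confidence-bound
#' acquisition (predicted mean + spread across trees) over a random
#' candidate pool. Every trial trains a model with [train_labeler()].
#'
#' @param space Named list of inclusive ranges: `K` (odd values only), `C`,
#'   `U`, `N`.
#' @param budget Total number of trials (default 20).
#' @param train,val Datasets for the trials.
#' @param tc A [train_config()].
#' @param L,dropout Fixed architecture settings for all trials.
#' @param seed Integer seed; the whole search is reproducible from it.
#' @param verbose Print per-trial lines.
#' @return A tibble ranked by decreasing validation MCC with columns
#'   `trial`, `K`, `C`, `U`, `N`, `val_mcc`, and a `model` list-column of
#'   trained labelers.
#' @export
tune_hyperparameters <- function(space = list(K = c(3L, 11L), C = c(16L, 128L),
                                              U = c(16L, 128L),
                                              N = c(32L, 256L)),
                                 budget = 20L, train, val,
                                 tc = train_config(), L = 200L, dropout = 0.1,
                                 seed = 1L, verbose = FALSE) {
  budget <- as.integer(budget)
  stopifnot(budget >= 1L)
  if (!all(c("K", "C", "U", "N") %in% names(space))) {
    stop("`space` must give ranges for K, C, U and N", call. = FALSE)
  }
  sample_cfg <- function() {
    ks <- seq(space$K[[1L]], space$K[[2L]])
    ks <- ks[ks %% 2L == 1L]
    list(K = sample(ks, 1L),
         C = sample(seq(space$C[[1L]], space$C[[2L]]), 1L),
         U = sample(seq(space$U[[1L]], space$U[[2L]]), 1L),
         N = sample(seq(space$N[[1L]], space$N[[2L]]), 1L))
  }
  evaluate_cfg <- function(cf, trial) {
    cfg <- model_config(cf$K, cf$C, cf$U, cf$N, L = L, dropout = dropout)
    mdl <- build_labeler(cfg, seed = seed + trial)
    mdl <- train_labeler(mdl, train, val, tc)
    list(model = mdl, mcc = mdl$val_metric)
  }
  withr_seed(seed, {
    n_init <- min(budget, 4L)
    trials <- vector("list", budget)
    for (trial in seq_len(budget)) {
      cf <- if (trial <= n_init) {
        sample_cfg()
      } else {
        obs <- dplyr::bind_rows(lapply(trials[seq_len(trial - 1L)], function(t) {
          tibble::tibble(K = t$K, C = t$C, U = t$U, N = t$N, y = t$val_mcc)
        }))
        cand <- dplyr::bind_rows(lapply(seq_len(64L),
                                        function(i) tibble::as_tibble(sample_cfg())))
        acq <- tryCatch({
          rf <- suppressWarnings(
            randomForest::randomForest(y ~ K + C + U + N, data = obs,
                                       ntree = 200L))
          pr <- stats::predict(rf, cand, predict.all = TRUE)
          pr$aggregate + apply(pr$individual, 1L, stats::sd)
        }, error = function(e) stats::runif(nrow(cand)))
        as.list(cand[which.max(acq), ])
      }
      res <- evaluate_cfg(cf, trial)
      trials[[trial]] <- tibble::tibble(
        trial = trial, K = cf$K, C = cf$C, U = cf$U, N = cf$N,
        val_mcc = res$mcc, model = list(res$model)
      )
      if (verbose) {
        cat(sprintf("trial %2d: K=%d C=%d U=%d N=%d -> val MCC %.4f\n",
                    trial, cf$K, cf$C, cf$U, cf$N, res$mcc))
      }
    }
  })
  dplyr::arrange(dplyr::bind_rows(trials), dplyr::desc(.data$val_mcc))
}

#' Ensemble of trained labelers
#'
#' Builds an ensemble from the top `k` models of a tuning table (ranked by
#' validation MCC) or from an explicit list of labelers. The ensemble
#' prediction for each base is the arithmetic mean of the members' class-1
#' probabilities.
#'
#' @param models A tibble from [tune_hyperparameters()] or a list of
#'   `rna_labeler` objects.
#' @param k Number of members to keep when `models` is a tuning table
#'   (default 3).
#' @return An object of class `rna_labeler_ensemble`.
#' @export
labeler_ensemble <- function(models, k = 3L) {
  selection <- NULL
  if (is.data.frame(models)) {
    ranked <- dplyr::arrange(models, dplyr::desc(.data$val_mcc))
    k <- min(k, nrow(ranked))
    selection <- dplyr::select(ranked[seq_len(k), ], -"model")
    members <- ranked$model[seq_len(k)]
  } else {
    members <- models
  }
  stopifnot(length(members) >= 1L,
            all(vapply(members, inherits, logical(1), "rna_labeler")))
  Ls <- vapply(members, function(m) m$config$L, integer(1))
  if (length(unique(Ls)) != 1L) {
    stop("ensemble members have mismatched window lengths: ",
         paste(unique(Ls), collapse = ", "), call. = FALSE)
  }
  structure(list(members = members, selection = selection, L = Ls[[1L]]),
            class = "rna_labeler_ensemble")
}

#' @export
print.rna_labeler_ensemble <- function(x, ...) {
  cat("Labeler ensemble with", length(x$members), "member(s), L =",
      x$L, "\n")
  invisible(x)
}

#' Per-window class-1 probabilities
#'
#' @param object An `rna_labeler` or `rna_labeler_ensemble`.
#' @param ws An `rna_window_set`, an `rna_window_dataset`, or a one-hot
#'   array `(n_windows, L, 5)`.
#' @return Numeric matrix `(n_windows, L)` of exterior probabilities (the
#'   mean over members for an ensemble).
#' @export
predict_window_probs <- function(object, ws) {
  inp <- coerce_windows(ws)
  if (inherits(object, "rna_labeler_ensemble")) {
    probs <- lapply(object$members, function(m) {
      predict_window_probs(m, ws)
    })
    return(Reduce(`+`, probs) / length(probs))
  }
  stopifnot(inherits(object, "rna_labeler"))
  if (dim(inp$x)[[2L]] != object$config$L) {
    stop("window length ", dim(inp$x)[[2L]], " does not match model L = ",
         object$config$L, call. = FALSE)
  }
  forward_in_chunks(object$params, object$buffers, object$config,
                    inp$x, inp$mask)
}

coerce_windows <- function(ws) {
  if (inherits(ws, "rna_window_set")) {
    list(x = encode_onehot(ws), mask = window_masks(ws) * 1L)
  } else if (inherits(ws, "rna_window_dataset")) {
    list(x = ws$x, mask = ws$mask)
  } else if (is.array(ws) && length(dim(ws)) == 3L) {
    list(x = ws, mask = matrix(1L, dim(ws)[[1L]], dim(ws)[[2L]]))
  } else {
    stop("cannot interpret `ws` as windows", call. = FALSE)
  }
}

#' Per-base exterior probabilities for a full sequence
#'
#' Windows the sequence at the model's window length, predicts each window,
#' and stitches overlapping predictions by averaging. Inference defaults to
#' a half-window step so interior bases are covered twice; dataset-style
#' non-overlapping windows (`step = L`) remain available.
#'
#' @param object An `rna_labeler` or `rna_labeler_ensemble`.
#' @param sequence RNA sequence (character scalar).
#' @param step Window step; default `ceiling(L / 2)`.
#' @return Numeric vector of per-base probabilities, length `nchar(sequence)`.
#' @export
predict_exterior_probs <- function(object, sequence, step = NULL) {
  L <- if (inherits(object, "rna_labeler_ensemble")) object$L else
    object$config$L
  step <- as.integer(step %||% ceiling(L / 2))
  ws <- make_windows(sequence, L = L, step = min(step, L))
  stitch_predictions(predict_window_probs(object, ws), ws)
}

#' Binarize probabilities into exterior labels
#'
#' @param probabilities Numeric vector/matrix in `[0, 1]`.
#' @param threshold Positive-class threshold in `[0, 1]`; a probability
#'   exactly at the threshold is labeled exterior (ties go to 1).
#' @return Integer 0/1 labels with the shape of the input.
#' @export
predict_labels <- function(probabilities, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold < 0 ||
      threshold > 1) {
    stop("`threshold` must be a single value in [0, 1]", call. = FALSE)
  }
  if (any(probabilities < 0 | probabilities > 1, na.rm = TRUE)) {
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  }
  out <- (probabilities >= threshold) * 1L
  storage.mode(out) <- "integer"
  out
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the training history of a labeler
#'
#' @param x A trained `rna_labeler`.
#' @param ... Unused.
#' @return The per-epoch history tibble.
#' @export
tidy.rna_labeler <- function(x, ...) {
  if (is.null(x$history)) {
    stop("labeler has no training history yet", call. = FALSE)
  }
  x$history
}

#' One-row summary of a labeler
#'
#' @param x An `rna_labeler`.
#' @param ... Unused.
#' @return A one-row tibble: architecture, parameter count, epochs trained,
#'   best validation MCC.
#' @export
glance.rna_labeler <- function(x, ...) {
  tibble::tibble(
    K = x$config$K, C = x$config$C, U = x$config$U, N = x$config$N,
    L = x$config$L, dropout = x$config$dropout,
    n_parameters = n_parameters(x),
    epochs = if (is.null(x$history)) 0L else nrow(x$history),
    val_mcc = x$val_metric %||% NA_real_
  )
}

#' Save / load a labeler checkpoint
#'
#' Checkpoints are a directory with a JSON manifest (architecture, training
#' summary) and flat text weight files, so they survive in plain-text form.
#'
#' @param x An `rna_labeler`.
#' @param path Checkpoint directory.
#' @return `path` (save) or an `rna_labeler` (load).
#' @export
save_labeler <- function(x, path) {
  stopifnot(inherits(x, "rna_labeler"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    config = unclass(x$config), trained = x$trained,
    init_seed = x$init_seed,
    val_metric = x$val_metric %||% NA_real_,
    params = lapply(x$params, function(p) dim(p) %||% length(p))
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  dump_num <- function(v, f) {
    writeLines(format(as.vector(v), digits = 17), file.path(path, f))
  }
  for (nm in names(x$params)) dump_num(x$params[[nm]], paste0(nm, ".txt"))
  for (nm in names(x$buffers)) dump_num(x$buffers[[nm]], paste0(nm, ".txt"))
  if (!is.null(x$history)) {
    utils::write.table(x$history, file.path(path, "history.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname save_labeler
#' @export
load_labeler <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  cfg <- do.call(model_config, manifest$config[c("K", "C", "U", "N", "L",
                                                 "dropout")])
  x <- build_labeler(cfg, seed = manifest$init_seed %||% 1L)
  read_num <- function(f) as.numeric(readLines(file.path(path, f)))
  for (nm in names(x$params)) {
    v <- read_num(paste0(nm, ".txt"))
    dim(v) <- dim(x$params[[nm]])
    x$params[[nm]] <- v
  }
  for (nm in names(x$buffers)) {
    x$buffers[[nm]] <- read_num(paste0(nm, ".txt"))
  }
  x$trained <- isTRUE(manifest$trained)
  x$val_metric <- manifest$val_metric
  hist_path <- file.path(path, "history.tsv")
  if (file.exists(hist_path)) {
    x$history <- tibble::as_tibble(utils::read.delim(hist_path))
  }
  x
}
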