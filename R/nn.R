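# Internal neural-network engine for the exterior-loop labeler.
#
# The architecture is fixed (4 x 1D-conv -> Bi-LSTM -> batch norm ->
# 2 ResNet layers -> batch norm -> per-position 2-way softmax), so the
# forward and backward passes are written out analytically and driven by
# BLAS-level matrix algebra; Adam does the updates. All activations live as
# flat (B*L, F) matrices in position-major blocks (row = b + (l-1)*B), which
# makes convolution an im2col matrix product, keeps the Bi-LSTM kernels
# (src/lstm.cpp) copy-free, and lets padding positions be zeroed by a single
# row mask after every block. Padding is likewise excluded from batch
# statistics and the loss.

glorot <- function(fan_in, fan_out, dims) {
  limit <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -limit, limit), dim = dims)
}

# Parameter initialisation for a model_config. Uses the current RNG state.
nn_init_params <- function(cfg) {
  K <- cfg$K; C <- cfg$C; U <- cfg$U; N <- cfg$N
  p <- list()
  c_in <- 5L
  for (l in 1:4) {
    p[[paste0("conv", l, "_W")]] <- glorot(K * c_in, C, c(K, c_in, C))
    p[[paste0("conv", l, "_b")]] <- numeric(C)
    c_in <- C
  }
  for (dir in c("f", "b")) {
    p[[paste0("lstm_", dir, "_W")]] <- glorot(C + U, 4L * U, c(C + U, 4L * U))
    bias <- numeric(4L * U)
    bias[U + seq_len(U)] <- 1 # forget-gate bias
    p[[paste0("lstm_", dir, "_b")]] <- bias
  }
  p$bn1_gamma <- rep(1, 2L * U); p$bn1_beta <- numeric(2L * U)
  p$res1_W1 <- glorot(2L * U, N, c(2L * U, N)); p$res1_b1 <- numeric(N)
  p$res1_W2 <- glorot(N, N, c(N, N));           p$res1_b2 <- numeric(N)
  p$res2_W1 <- glorot(N, N, c(N, N));           p$res2_b1 <- numeric(N)
  p$res2_W2 <- glorot(N, N, c(N, N));           p$res2_b2 <- numeric(N)
  p$bn2_gamma <- rep(1, N); p$bn2_beta <- numeric(N)
  p$out_W <- glorot(N, 2L, c(N, 2L)); p$out_b <- numeric(2L)
  p
}

nn_init_buffers <- function(cfg) {
  list(bn1_rmean = numeric(2L * cfg$U), bn1_rvar = rep(1, 2L * cfg$U),
       bn2_rmean = numeric(cfg$N), bn2_rvar = rep(1, cfg$N))
}

# (B, L, F) array -> (B*L, F) matrix; rows come out position-major because R
# arrays are column-major.
flat2 <- function(x) {
  d <- dim(x)
  dim(x) <- c(d[[1L]] * d[[2L]], d[[3L]])
  x
}

# column-wise broadcast helpers (C++ single-pass; sweep() transposes)
addcol <- function(x, v) addcol_cpp(x, v)
mulcol <- function(x, v) mulcol_cpp(x, v)

# (K, Cin, Cout) kernel -> (K*Cin, Cout) matrix with rows (t, c) ordered
# c-fastest, matching the conv kernels' tap blocks.
conv_weight_mat <- function(W) {
  d <- dim(W)
  matrix(aperm(W, c(2L, 1L, 3L)), d[[1L]] * d[[2L]], d[[3L]])
}

conv_weight_unmat <- function(M, K, Cin, Cout) {
  aperm(array(M, dim = c(Cin, K, Cout)), c(2L, 1L, 3L))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

apply_dropout <- function(xf, dm) if (is.null(dm)) xf else xf * dm

# Full forward pass. X: (B, L, 5) one-hot, mask: (B, L) in {0,1}.
# Returns class probabilities (B, L, 2) and, when `want_cache`, everything
# the backward pass needs. Buffers (running BN stats) are updated when
# training.
nn_forward <- function(params, buffers, cfg, X, mask, training = FALSE,
                       want_cache = FALSE) {
  B <- dim(X)[[1L]]; L <- dim(X)[[2L]]
  stopifnot(L == cfg$L)
  # flat row order is position-major: row b + (l-1)*B
  mrow <- as.vector(matrix(mask, nrow = B))
  drop <- cfg$dropout
  cache <- list(mrow = mrow, B = B, L = L)
  # mask the raw input so padding content can never leak in
  hf <- flat2(X) * mrow
  cache$conv_in <- vector("list", 4L)
  cache$conv_pos <- vector("list", 4L)
  cache$conv_dm <- vector("list", 4L)
  for (l in 1:4) {
    cache$conv_in[l] <- list(if (want_cache) hf else NULL)
    cf <- conv_fwd_cpp(hf, B, L,
                       conv_weight_mat(params[[paste0("conv", l, "_W")]]),
                       params[[paste0("conv", l, "_b")]], mrow,
                       drop, training)
    cache$conv_pos[l] <- list(cf$pos)
    cache$conv_dm[l] <- list(cf$dm)
    hf <- cf$a
  }
  cache$lstm_in <- hf
  fwd <- lstm_forward_cpp(hf, B, L, params$lstm_f_W, params$lstm_f_b, FALSE)
  bwd <- lstm_forward_cpp(hf, B, L, params$lstm_b_W, params$lstm_b_b, TRUE)
  cache$lstm_f <- fwd; cache$lstm_b <- bwd
  hf <- cbind(fwd$hs, bwd$hs) * mrow
  dm <- if (training && drop > 0) {
    dropout_mask_cpp(nrow(hf), ncol(hf), drop)
  } else NULL
  cache$lstm_dm <- dm
  hf <- apply_dropout(hf, dm)
  bn1 <- bn_fwd_cpp(hf, mrow, params$bn1_gamma, params$bn1_beta,
                    buffers$bn1_rmean, buffers$bn1_rvar, training,
                    1e-5, 0.9)
  if (training) {
    buffers$bn1_rmean <- as.vector(bn1$rmean)
    buffers$bn1_rvar <- as.vector(bn1$rvar)
  }
  cache$bn1 <- bn1
  hf <- bn1$y * mrow
  cache$res <- vector("list", 2L)
  for (r in 1:2) {
    W1 <- params[[paste0("res", r, "_W1")]]
    b1 <- params[[paste0("res", r, "_b1")]]
    W2 <- params[[paste0("res", r, "_W2")]]
    b2 <- params[[paste0("res", r, "_b2")]]
    rp1 <- relu_post_cpp(hf %*% W1, b1, mrow, NULL)
    h1 <- rp1$a
    rp2 <- relu_post_cpp(h1 %*% W2, b2, mrow, NULL)
    out <- h1 + rp2$a
    dm <- if (training && drop > 0) {
      dropout_mask_cpp(nrow(out), ncol(out), drop)
    } else NULL
    cache$res[[r]] <- list(xin = hf, z1pos = rp1$pos, h1 = h1,
                           z2pos = rp2$pos, dm = dm)
    hf <- apply_dropout(out, dm)
  }
  bn2 <- bn_fwd_cpp(hf, mrow, params$bn2_gamma, params$bn2_beta,
                    buffers$bn2_rmean, buffers$bn2_rvar, training,
                    1e-5, 0.9)
  if (training) {
    buffers$bn2_rmean <- as.vector(bn2$rmean)
    buffers$bn2_rvar <- as.vector(bn2$rvar)
  }
  cache$bn2 <- bn2
  hf <- bn2$y * mrow
  cache$out_in <- hf
  logits <- addcol(hf %*% params$out_W, params$out_b)
  mx <- pmax(logits[, 1L], logits[, 2L])
  e1 <- exp(logits[, 1L] - mx); e2 <- exp(logits[, 2L] - mx)
  probs <- cbind(e1, e2) / (e1 + e2)
  cache$probs <- probs
  probs_arr <- probs
  dim(probs_arr) <- c(B, L, 2L)
  list(probs = probs_arr, buffers = buffers,
       cache = if (want_cache) cache else NULL)
}

# Masked cross-entropy loss and full gradient. `y` is (B, L) 0/1.
nn_backward <- function(params, cfg, y, cache) {
  mrow <- cache$mrow
  B <- cache$B; L <- cache$L
  nm <- sum(mrow)
  yv <- as.vector(matrix(y, nrow = B)) # flat row order
  probs <- cache$probs
  eps <- 1e-12
  loss <- -sum(log(pmax(probs[cbind(seq_along(yv), yv + 1L)], eps)) *
                 mrow) / nm
  g <- list()
  dlogits <- (probs - cbind(1 - yv, yv)) * mrow / nm
  g$out_W <- crossprod(cache$out_in, dlogits)
  g$out_b <- colSums(dlogits)
  dhf <- (dlogits %*% t(params$out_W)) * mrow
  bb <- bn_bwd_cpp(dhf, cache$bn2$xhat, cache$bn2$inv, params$bn2_gamma,
                   mrow, TRUE)
  g$bn2_gamma <- as.vector(bb$dgamma); g$bn2_beta <- as.vector(bb$dbeta)
  dhf <- bb$dx
  for (r in 2:1) {
    rc <- cache$res[[r]]
    dout <- rowmask_cpp(apply_dropout(dhf, rc$dm), mrow)
    dz2 <- dout * rc$z2pos
    dh1 <- dout + dz2 %*% t(params[[paste0("res", r, "_W2")]])
    dz1 <- dh1 * rc$z1pos
    g[[paste0("res", r, "_W2")]] <- crossprod(rc$h1, dz2)
    g[[paste0("res", r, "_b2")]] <- colSums(dz2)
    g[[paste0("res", r, "_W1")]] <- crossprod(rc$xin, dz1)
    g[[paste0("res", r, "_b1")]] <- colSums(dz1)
    dhf <- dz1 %*% t(params[[paste0("res", r, "_W1")]])
  }
  dhf <- dhf * mrow
  bb <- bn_bwd_cpp(dhf, cache$bn1$xhat, cache$bn1$inv, params$bn1_gamma,
                   mrow, TRUE)
  g$bn1_gamma <- as.vector(bb$dgamma); g$bn1_beta <- as.vector(bb$dbeta)
  dhf <- apply_dropout(bb$dx, cache$lstm_dm) * mrow
  U <- cfg$U
  bf <- lstm_backward_cpp(cache$lstm_in, B, L, params$lstm_f_W,
                          cache$lstm_f$hs, cache$lstm_f$cs,
                          cache$lstm_f$tcs, cache$lstm_f$gates,
                          dhf[, seq_len(U), drop = FALSE], FALSE)
  bbk <- lstm_backward_cpp(cache$lstm_in, B, L, params$lstm_b_W,
                           cache$lstm_b$hs, cache$lstm_b$cs,
                           cache$lstm_b$tcs, cache$lstm_b$gates,
                           dhf[, U + seq_len(U), drop = FALSE], TRUE)
  g$lstm_f_W <- bf$dW; g$lstm_f_b <- as.vector(bf$db)
  g$lstm_b_W <- bbk$dW; g$lstm_b_b <- as.vector(bbk$db)
  dh <- bf$dx + bbk$dx
  K <- cfg$K
  for (l in 4:1) {
    W <- params[[paste0("conv", l, "_W")]]
    cb <- conv_bwd_cpp(dh, cache$conv_dm[[l]], mrow, cache$conv_pos[[l]],
                       cache$conv_in[[l]], conv_weight_mat(W), B, L)
    Cin <- dim(W)[[2L]]
    g[[paste0("conv", l, "_W")]] <- conv_weight_unmat(cb$dW, K, Cin,
                                                      dim(W)[[3L]])
    g[[paste0("conv", l, "_b")]] <- as.vector(cb$db)
    dh <- cb$dx
  }
  list(loss = loss, grads = g)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       v = lapply(params, function(p) array(0, dim = dim(p) %||% length(p))),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gnm
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gnm^2
    step <- lr * (state$m[[nm]] / bc1) /
      (sqrt(state$v[[nm]] / bc2) + eps)
    pn <- params[[nm]] - as.vector(step)
    dim(pn) <- dim(params[[nm]])
    params[[nm]] <- pn
  }
  list(params = params, state = state)
}
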