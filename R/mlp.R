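# Compact feedforward classifier: dense layers, tanh/ReLU hidden
# activations, softmax output, cross-entropy loss with L2 penalty, Adam
# updates, mini-batches, and early stopping on a held-out validation split.
# This is the edge-deployment model of the pipeline; defaults follow the
# tuned configuration (256-128 tanh, lr 0.001, batch 32, alpha 0.001,
# patience 10, <= 500 epochs). Internal: called via train_model().

mlp_fit <- function(X, y_int, K, hidden = c(256L, 128L),
                    activation = c("tanh", "relu"), learning_rate = 0.001,
                    batch_size = 32L, alpha = 0.001, patience = 10L,
                    max_epochs = 500L, val_fraction = 0.1, tol = 1e-4) {
  activation <- match.arg(activation)
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)

  # stratified validation split for early stopping
  val_idx <- integer(0)
  if (val_fraction > 0) {
    for (k in unique(y_int)) {
      rows <- which(y_int == k)
      n_val <- max(1L, floor(length(rows) * val_fraction))
      if (length(rows) > n_val)
        val_idx <- c(val_idx, sample(rows, n_val))
    }
  }
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; ytr <- y_int[tr_idx]
  Xval <- X[val_idx, , drop = FALSE]; yval <- y_int[val_idx]

  sizes <- c(p, hidden, K)
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {        # Glorot uniform
    lim <- sqrt(6 / (sizes[l] + sizes[l + 1L]))
    W[[l]] <- matrix(stats::runif(sizes[l] * sizes[l + 1L], -lim, lim),
                     sizes[l], sizes[l + 1L])
    b[[l]] <- numeric(sizes[l + 1L])
  }
  mW <- lapply(W, function(w) w * 0); vW <- mW
  mb <- lapply(b, function(x) x * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; step <- 0

  act <- if (activation == "tanh") tanh else function(z) pmax(z, 0)
  act_grad <- if (activation == "tanh") function(a) 1 - a^2 else
    function(a) (a > 0) * 1

  forward <- function(Xb) {
    A <- vector("list", L + 1L)
    A[[1L]] <- Xb
    for (l in seq_len(L - 1L))
      A[[l + 1L]] <- act(sweep(A[[l]] %*% W[[l]], 2L, b[[l]], `+`))
    A[[L + 1L]] <- softmax_rows(sweep(A[[L]] %*% W[[L]], 2L, b[[L]], `+`))
    A
  }
  ce_loss <- function(P, yk) {
    -mean(log(pmax(P[cbind(seq_along(yk), yk + 1L)], 1e-12)))
  }

  ntr <- nrow(Xtr)
  best_loss <- Inf; best <- NULL; stall <- 0L
  for (epoch in seq_len(max_epochs)) {
    ord <- sample.int(ntr)
    for (start in seq(1L, ntr, by = batch_size)) {
      rows <- ord[start:min(start + batch_size - 1L, ntr)]
      nb <- length(rows)
      A <- forward(Xtr[rows, , drop = FALSE])
      Yb <- matrix(0, nb, K)
      Yb[cbind(seq_len(nb), ytr[rows] + 1L)] <- 1
      delta <- (A[[L + 1L]] - Yb) / nb
      step <- step + 1L
      for (l in rev(seq_len(L))) {
        gW <- crossprod(A[[l]], delta) + (alpha / nb) * W[[l]]
        gb <- colSums(delta)
        if (l > 1L)
          delta <- (delta %*% t(W[[l]])) * act_grad(A[[l]])
        mW[[l]] <- beta1 * mW[[l]] + (1 - beta1) * gW
        vW[[l]] <- beta2 * vW[[l]] + (1 - beta2) * gW^2
        mb[[l]] <- beta1 * mb[[l]] + (1 - beta1) * gb
        vb[[l]] <- beta2 * vb[[l]] + (1 - beta2) * gb^2
        mhat <- mW[[l]] / (1 - beta1^step)
        vhat <- vW[[l]] / (1 - beta2^step)
        W[[l]] <- W[[l]] - learning_rate * mhat / (sqrt(vhat) + eps)
        mbh <- mb[[l]] / (1 - beta1^step)
        vbh <- vb[[l]] / (1 - beta2^step)
        b[[l]] <- b[[l]] - learning_rate * mbh / (sqrt(vbh) + eps)
      }
    }
    mon <- if (length(val_idx)) ce_loss(forward(Xval)[[L + 1L]], yval) else
      ce_loss(forward(Xtr)[[L + 1L]], ytr)
    if (mon < best_loss - tol) {
      best_loss <- mon; stall <- 0L
      best <- list(W = W, b = b)
    } else {
      stall <- stall + 1L
      if (stall >= patience) break
    }
  }
  if (!is.null(best)) { W <- best$W; b <- best$b }
  list(W = W, b = b, activation = activation, K = K, hidden = hidden,
       epochs = epoch, val_loss = best_loss)
}

mlp_prob <- function(fit, X) {
  A <- as.matrix(X)
  L <- length(fit$W)
  act <- if (fit$activation == "tanh") tanh else function(z) pmax(z, 0)
  for (l in seq_len(L - 1L))
    A <- act(sweep(A %*% fit$W[[l]], 2L, fit$b[[l]], `+`))
  softmax_rows(sweep(A %*% fit$W[[L]], 2L, fit$b[[L]], `+`))
}

mlp_n_params <- function(fit)
  sum(vapply(fit$W, length, 0)) + sum(vapply(fit$b, length, 0))
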