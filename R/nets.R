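# Small hand-written neural networks for sequence staging.  Three
# variants share a weighted softmax cross-entropy head:
#   conv           - 1-D convolution over the (ordered) feature axis
#                    within an epoch, ReLU, mean-pool over positions,
#                    dense softmax; each epoch classified independently.
#   recurrent      - Elman RNN over the epoch sequence on the raw
#                    feature vectors, softmax per epoch.
#   conv_recurrent - the conv encoder feeding the RNN.
# Training is full-batch Adam with analytic gradients, so a fixed seed
# and fixed data give bit-identical parameters and predictions.

net_init <- function(variant, d, cfg) {
  k <- cfg$kernel; f <- cfg$filters; h <- cfg$hidden
  g <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = 1 / sqrt(nr)), nr, nc)
  p <- switch(variant,
    conv = list(W1 = g(k, f), b1 = numeric(f),
                W2 = g(2 * f, 5), b2 = numeric(5)),
    recurrent = list(A = g(d, h), U = g(h, h) * 0.5, b = numeric(h),
                     C = g(h, 5), c0 = numeric(5)),
    conv_recurrent = list(W1 = g(k, f), b1 = numeric(f),
                          A = g(2 * f, h), U = g(h, h) * 0.5, b = numeric(h),
                          C = g(h, 5), c0 = numeric(5)),
    abort_config(sprintf("unknown variant: %s", variant)))
  p
}

n_params <- function(params) sum(vapply(params, length, integer(1)))

# im2col for the 1-D conv: rows indexed (sample, position) with the
# sample index fastest, columns the kernel taps.
conv_cols <- function(X, k) {
  d <- ncol(X); P <- d - k + 1L
  out <- matrix(0, nrow(X) * P, k)
  for (i in seq_len(k)) out[, i] <- as.vector(X[, i:(i + P - 1L), drop = FALSE])
  out
}

# Encoder output concatenates mean- and max-pooling over positions
# (2*filters dims): the mean carries broad spectral profile, the max
# responds to isolated strong activations.
conv_encode <- function(Xcol, n, P, params) {
  Z <- sweep(Xcol %*% params$W1, 2, params$b1, `+`)
  A <- pmax(Z, 0)
  f <- ncol(A)
  M <- matrix(0, n, 2 * f)
  amax <- matrix(0L, n, f)
  for (j in seq_len(f)) {
    Aj <- matrix(A[, j], n, P)
    M[, j] <- rowMeans(Aj)
    jm <- max.col(Aj, ties.method = "first")
    amax[, j] <- jm
    M[, f + j] <- Aj[cbind(seq_len(n), jm)]
  }
  list(Z = Z, M = M, amax = amax)
}

conv_encode_grad <- function(Xcol, enc, dM, n, P) {
  f <- ncol(enc$amax)
  dA <- dM[rep(seq_len(n), times = P), seq_len(f), drop = FALSE] / P
  for (j in seq_len(f)) {
    rows <- (enc$amax[, j] - 1L) * n + seq_len(n)
    dA[rows, j] <- dA[rows, j] + dM[, f + j]
  }
  dZ <- dA * (enc$Z > 0)
  list(dW1 = crossprod(Xcol, dZ), db1 = colSums(dZ))
}

softmax_rows <- function(L) {
  L <- L - apply(L, 1, max)
  E <- exp(L)
  E / rowSums(E)
}

# Weighted cross-entropy loss + dlogits for one-hot Y and per-sample
# weights w (normalised inside).
ce_loss <- function(P, Y, w) {
  sw <- sum(w)
  loss <- -sum(w * log(pmax(rowSums(P * Y), 1e-12))) / sw
  dlog <- (P - Y) * (w / sw)
  list(loss = loss, dlogits = dlog)
}

rnn_forward <- function(E, params) {
  T_ <- nrow(E); h <- length(params$b)
  H <- matrix(0, T_, h)
  hp <- numeric(h)
  for (t in seq_len(T_)) {
    hp <- tanh(drop(E[t, ] %*% params$A) + drop(hp %*% params$U) + params$b)
    H[t, ] <- hp
  }
  H
}

rnn_backward <- function(E, H, dH, params) {
  T_ <- nrow(E); h <- ncol(H)
  dA <- params$A * 0; dU <- params$U * 0; db <- numeric(h)
  dE <- E * 0
  delta <- numeric(h)
  for (t in rev(seq_len(T_))) {
    dh <- dH[t, ] + delta
    da <- dh * (1 - H[t, ]^2)
    dA <- dA + outer(E[t, ], da)
    hprev <- if (t > 1L) H[t - 1L, ] else numeric(h)
    dU <- dU + outer(hprev, da)
    db <- db + da
    dE[t, ] <- da %*% t(params$A)
    delta <- drop(params$U %*% da)
  }
  list(dA = dA, dU = dU, db = db, dE = dE)
}

# Forward pass + (optionally) gradients over a list of subject
# sequences.  Xs: list of T_i x d matrices; Ys: list of one-hot; ws:
# list of per-epoch weights.
net_pass <- function(variant, params, Xs, Ys, ws, cfg, grad = TRUE) {
  k <- cfg$kernel
  zero <- lapply(params, function(p) p * 0)
  grads <- zero
  total_loss <- 0; total_w <- 0
  preds <- vector("list", length(Xs))
  for (s in seq_along(Xs)) {
    X <- Xs[[s]]
    n <- nrow(X); P <- ncol(X) - k + 1L
    if (variant %in% c("conv", "conv_recurrent")) {
      Xcol <- conv_cols(X, k)
      enc <- conv_encode(Xcol, n, P, params)
    }
    inp <- switch(variant, conv = enc$M, recurrent = X, conv_recurrent = enc$M)
    if (variant == "conv") {
      logits <- sweep(inp %*% params$W2, 2, params$b2, `+`)
    } else {
      H <- rnn_forward(inp, params)
      logits <- sweep(H %*% params$C, 2, params$c0, `+`)
    }
    Pm <- softmax_rows(logits)
    preds[[s]] <- max.col(Pm, ties.method = "first")
    if (is.null(Ys)) next
    w <- ws[[s]]
    sw <- sum(w)
    cl <- ce_loss(Pm, Ys[[s]], w)
    total_loss <- total_loss + cl$loss * sw
    total_w <- total_w + sw
    if (!grad) next
    dlog <- cl$dlogits * sw   # re-scale; normalised at the end
    if (variant == "conv") {
      grads$W2 <- grads$W2 + crossprod(inp, dlog)
      grads$b2 <- grads$b2 + colSums(dlog)
      dM <- dlog %*% t(params$W2)
      cg <- conv_encode_grad(Xcol, enc, dM, n, P)
      grads$W1 <- grads$W1 + cg$dW1
      grads$b1 <- grads$b1 + cg$db1
    } else {
      grads$C <- grads$C + crossprod(H, dlog)
      grads$c0 <- grads$c0 + colSums(dlog)
      dH <- dlog %*% t(params$C)
      rb <- rnn_backward(inp, H, dH, params)
      grads$A <- grads$A + rb$dA
      grads$U <- grads$U + rb$dU
      grads$b <- grads$b + rb$db
      if (variant == "conv_recurrent") {
        cg <- conv_encode_grad(Xcol, enc, rb$dE, n, P)
        grads$W1 <- grads$W1 + cg$dW1
        grads$b1 <- grads$b1 + cg$db1
      }
    }
  }
  if (!is.null(Ys) && total_w > 0) {
    total_loss <- total_loss / total_w
    if (grad) grads <- lapply(grads, function(g) g / total_w)
  }
  list(loss = total_loss, grads = if (grad) grads else NULL, preds = preds)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, l2 = 0) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]] + l2 * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mh <- state$m[[nm]] / (1 - beta1^state$t)
    vh <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
  }
  list(params = params, state = state)
}
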