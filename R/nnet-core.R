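# Native neural-network engine
#
# Minimal, fully deterministic implementations of the two binary text
# classifiers used by this package:
#
#   cnn : embedding -> dropout -> 1-D convolution (valid padding, ReLU)
#         -> global average pooling -> dense (ReLU) -> dropout
#         -> dense(1, sigmoid)
#   lstm: embedding -> (input dropout) -> LSTM -> dense(1, sigmoid)
#
# trained by mini-batch Adam on binary cross-entropy. Everything runs on
# base-R matrix algebra; all randomness (initialization, shuffling, dropout
# masks) flows through R's global RNG so a single set.seed() makes runs
# reproducible. Token index 0 is the padding index; its embedding row is
# trained like any other (no masking), matching the common default of the
# layer family these architectures come from.
#
# Internal layout conventions: a batch of token matrices X (n x L) is
# embedded into a (n*L) x d matrix whose row (t-1)*n + i holds token t of
# sample i, i.e. sample index varies fastest. The im2col trick turns the
# 1-D convolution into a single matrix product.

.glorot <- function(fan_in, fan_out, nrow, ncol) {
  lim <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(nrow * ncol, -lim, lim), nrow, ncol)
}

.nn_init <- function(spec, vocab_size) {
  d <- spec$embedding_dim
  p <- list(E = matrix(stats::runif(vocab_size * d, -0.05, 0.05),
                       vocab_size, d))
  if (spec$kind == "cnn") {
    k <- spec$conv_kernel; f <- spec$conv_filters; h <- spec$hidden_units
    p$Wc <- .glorot(k * d, f, k * d, f)
    p$bc <- matrix(0, 1, f)
    p$W1 <- .glorot(f, h, f, h)
    p$b1 <- matrix(0, 1, h)
    p$W2 <- .glorot(h, 1, h, 1)
    p$b2 <- matrix(0, 1, 1)
  } else {
    u <- spec$lstm_units
    p$Wx <- .glorot(d, u, d, 4 * u)
    p$Wh <- .glorot(u, u, u, 4 * u)
    b <- matrix(0, 1, 4 * u)
    b[1, (u + 1):(2 * u)] <- 1  # forget-gate bias starts open
    p$b <- b
    p$W2 <- .glorot(u, 1, u, 1)
    p$b2 <- matrix(0, 1, 1)
  }
  p
}

.sigmoid <- function(x) 1 / (1 + exp(-x))

.bce <- function(p, y) {
  p <- pmin(pmax(p, 1e-7), 1 - 1e-7)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# ---- CNN -------------------------------------------------------------------

.cnn_forward <- function(params, X, spec, training = FALSE) {
  n <- nrow(X); L <- ncol(X)
  d <- spec$embedding_dim; k <- spec$conv_kernel; f <- spec$conv_filters
  rate <- spec$dropout
  if (L < k) {  # pad batch up to one kernel window
    X <- cbind(X, matrix(0L, n, k - L)); L <- k
  }
  Lo <- L - k + 1L

  H <- params$E[as.vector(X) + 1L, , drop = FALSE]      # (n*L) x d
  maskE <- NULL
  if (training && rate > 0) {
    maskE <- matrix(stats::runif(length(H)) >= rate, nrow(H), ncol(H))
    H <- H * maskE / (1 - rate)
  }

  Xc <- matrix(0, n * Lo, k * d)                        # im2col
  for (j in seq_len(k))
    Xc[, ((j - 1L) * d + 1L):(j * d)] <-
      H[((j - 1L) * n + 1L):((j + Lo - 1L) * n), , drop = FALSE]

  Zc <- sweep(Xc %*% params$Wc, 2, params$bc, `+`)      # (n*Lo) x f
  A <- Zc * (Zc > 0)
  A3 <- array(A, c(n, Lo, f))
  P <- colMeans(aperm(A3, c(2, 1, 3)))                  # n x f
  if (f == 1L) P <- matrix(P, ncol = 1L)

  Z1 <- sweep(P %*% params$W1, 2, params$b1, `+`)
  H1 <- Z1 * (Z1 > 0)
  mask1 <- NULL
  if (training && rate > 0) {
    mask1 <- matrix(stats::runif(length(H1)) >= rate, nrow(H1), ncol(H1))
    H1 <- H1 * mask1 / (1 - rate)
  }
  prob <- .sigmoid(sweep(H1 %*% params$W2, 2, params$b2, `+`))

  list(prob = as.vector(prob),
       cache = list(X = X, n = n, L = L, Lo = Lo, H = H, maskE = maskE,
                    Xc = Xc, Zc = Zc, P = P, Z1 = Z1, H1 = H1,
                    mask1 = mask1))
}

.cnn_backward <- function(params, cache, y, spec) {
  n <- cache$n; Lo <- cache$Lo; L <- cache$L
  d <- spec$embedding_dim; k <- spec$conv_kernel
  rate <- spec$dropout
  prob <- .sigmoid(sweep(cache$H1 %*% params$W2, 2, params$b2, `+`))

  dz2 <- (prob - y) / n                                  # n x 1
  g <- list()
  g$W2 <- crossprod(cache$H1, dz2)
  g$b2 <- matrix(colSums(dz2), 1)
  dH1 <- dz2 %*% t(params$W2)
  if (!is.null(cache$mask1)) dH1 <- dH1 * cache$mask1 / (1 - rate)
  dZ1 <- dH1 * (cache$Z1 > 0)
  g$W1 <- crossprod(cache$P, dZ1)
  g$b1 <- matrix(colSums(dZ1), 1)
  dP <- dZ1 %*% t(params$W1)

  dA <- dP[rep(seq_len(n), Lo), , drop = FALSE] / Lo     # pool backward
  dZc <- dA * (cache$Zc > 0)
  g$Wc <- crossprod(cache$Xc, dZc)
  g$bc <- matrix(colSums(dZc), 1)
  dXc <- dZc %*% t(params$Wc)

  dH <- matrix(0, n * L, d)
  for (j in seq_len(k)) {
    rows <- ((j - 1L) * n + 1L):((j + Lo - 1L) * n)
    dH[rows, ] <- dH[rows, ] + dXc[, ((j - 1L) * d + 1L):(j * d)]
  }
  if (!is.null(cache$maskE)) dH <- dH * cache$maskE / (1 - rate)

  idx <- as.vector(cache$X) + 1L
  acc <- rowsum(dH, group = idx)                         # by embedding row
  gE <- matrix(0, nrow(params$E), d)
  gE[as.integer(rownames(acc)), ] <- acc
  g$E <- gE
  g
}

# ---- LSTM ------------------------------------------------------------------

.lstm_forward <- function(params, X, spec, training = FALSE) {
  n <- nrow(X); L <- ncol(X)
  d <- spec$embedding_dim; u <- spec$lstm_units
  rate <- spec$dropout
  H <- params$E[as.vector(X) + 1L, , drop = FALSE]       # (n*L) x d
  maskX <- NULL
  if (training && rate > 0)  # one input mask shared across timesteps
    maskX <- matrix(stats::runif(n * d) >= rate, n, d)

  gi <- gf <- gg <- go <- Ct <- Tc <- array(0, c(n, u, L))
  Hs <- array(0, c(n, u, L + 1L))                        # h_0 in slice 1
  h <- matrix(0, n, u); cc <- matrix(0, n, u)
  iu <- 1:u; fu <- (u + 1):(2 * u); gu <- (2 * u + 1):(3 * u)
  ou <- (3 * u + 1):(4 * u)
  for (t in seq_len(L)) {
    xt <- H[((t - 1L) * n + 1L):(t * n), , drop = FALSE]
    if (!is.null(maskX)) xt <- xt * maskX / (1 - rate)
    Z <- sweep(xt %*% params$Wx + h %*% params$Wh, 2, params$b, `+`)
    i_ <- .sigmoid(Z[, iu, drop = FALSE])
    f_ <- .sigmoid(Z[, fu, drop = FALSE])
    g_ <- tanh(Z[, gu, drop = FALSE])
    o_ <- .sigmoid(Z[, ou, drop = FALSE])
    cc <- f_ * cc + i_ * g_
    tc <- tanh(cc)
    h <- o_ * tc
    gi[, , t] <- i_; gf[, , t] <- f_; gg[, , t] <- g_; go[, , t] <- o_
    Ct[, , t] <- cc; Tc[, , t] <- tc; Hs[, , t + 1L] <- h
  }
  prob <- .sigmoid(sweep(h %*% params$W2, 2, params$b2, `+`))
  list(prob = as.vector(prob),
       cache = list(X = X, n = n, L = L, H = H, maskX = maskX,
                    gi = gi, gf = gf, gg = gg, go = go, Ct = Ct, Tc = Tc,
                    Hs = Hs, h_last = h))
}

.lstm_backward <- function(params, cache, y, spec) {
  n <- cache$n; L <- cache$L
  d <- spec$embedding_dim; u <- spec$lstm_units
  rate <- spec$dropout
  prob <- .sigmoid(sweep(cache$h_last %*% params$W2, 2, params$b2, `+`))

  dz2 <- (prob - y) / n
  g <- list()
  g$W2 <- crossprod(cache$h_last, dz2)
  g$b2 <- matrix(colSums(dz2), 1)

  dh <- dz2 %*% t(params$W2)
  dc <- matrix(0, n, u)
  gWx <- matrix(0, d, 4 * u); gWh <- matrix(0, u, 4 * u)
  gb <- matrix(0, 1, 4 * u)
  dH <- matrix(0, n * L, d)
  iu <- 1:u; fu <- (u + 1):(2 * u); gu <- (2 * u + 1):(3 * u)
  ou <- (3 * u + 1):(4 * u)
  for (t in rev(seq_len(L))) {
    i_ <- cache$gi[, , t, drop = FALSE]; dim(i_) <- c(n, u)
    f_ <- cache$gf[, , t, drop = FALSE]; dim(f_) <- c(n, u)
    g_ <- cache$gg[, , t, drop = FALSE]; dim(g_) <- c(n, u)
    o_ <- cache$go[, , t, drop = FALSE]; dim(o_) <- c(n, u)
    tc <- cache$Tc[, , t, drop = FALSE]; dim(tc) <- c(n, u)
    cprev <- if (t > 1L) {
      z <- cache$Ct[, , t - 1L, drop = FALSE]; dim(z) <- c(n, u); z
    } else matrix(0, n, u)
    hprev <- cache$Hs[, , t, drop = FALSE]; dim(hprev) <- c(n, u)

    dc <- dc + dh * o_ * (1 - tc^2)
    dpo <- dh * tc * o_ * (1 - o_)
    dpi <- dc * g_ * i_ * (1 - i_)
    dpf <- dc * cprev * f_ * (1 - f_)
    dpg <- dc * i_ * (1 - g_^2)
    dZ <- matrix(0, n, 4 * u)
    dZ[, iu] <- dpi; dZ[, fu] <- dpf; dZ[, gu] <- dpg; dZ[, ou] <- dpo

    xt <- cache$H[((t - 1L) * n + 1L):(t * n), , drop = FALSE]
    if (!is.null(cache$maskX)) xt <- xt * cache$maskX / (1 - rate)
    gWx <- gWx + crossprod(xt, dZ)
    gWh <- gWh + crossprod(hprev, dZ)
    gb <- gb + matrix(colSums(dZ), 1)

    dxt <- dZ %*% t(params$Wx)
    if (!is.null(cache$maskX)) dxt <- dxt * cache$maskX / (1 - rate)
    dH[((t - 1L) * n + 1L):(t * n), ] <- dxt
    dh <- dZ %*% t(params$Wh)
    dc <- dc * f_
  }
  g$Wx <- gWx; g$Wh <- gWh; g$b <- gb

  idx <- as.vector(cache$X) + 1L
  acc <- rowsum(dH, group = idx)
  gE <- matrix(0, nrow(params$E), d)
  gE[as.integer(rownames(acc)), ] <- acc
  g$E <- gE
  g
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state,
                       lr = 0.001, beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(params)) {
    gmat <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * gmat
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * gmat^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

.nn_forward <- function(params, X, spec, training = FALSE) {
  if (spec$kind == "cnn") .cnn_forward(params, X, spec, training)
  else .lstm_forward(params, X, spec, training)
}

.nn_backward <- function(params, cache, y, spec) {
  if (spec$kind == "cnn") .cnn_backward(params, cache, y, spec)
  else .lstm_backward(params, cache, y, spec)
}
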