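# A small 1-D convolutional network for 297-point peak feature vectors:
# six convolution + max-pool blocks, one extra max-pool, and a single
# fully-connected sigmoid output. Forward pass via im2col matrix products,
# gradients by hand, Adam updates. Everything is base R; a finite-difference
# gradient check in the test suite guards the backward pass.

#' Network architecture specification
#'
#' Six convolution (+ ReLU) + max-pool blocks followed by an additional
#' max-pool and a fully-connected layer with a sigmoidal score in \[0, 1\].
#' Kernel size and per-block channel widths are configurable; defaults
#' reduce the 297-sample input to a 2-sample, 32-channel map before the
#' head.
#'
#' @param input_length Input length (default 297).
#' @param kernel_size Odd convolution kernel size (default 3; same-padding).
#' @param channel_widths Output channels of the six blocks.
#' @return Object of class `network_spec`.
#' @export
network_spec <- function(input_length = 297L, kernel_size = 3L,
                         channel_widths = c(8L, 16L, 32L, 32L, 32L, 32L)) {
  if (kernel_size %% 2L != 1L) stop_invalid("`kernel_size` must be odd")
  lens <- integer(length(channel_widths) + 1L)
  len <- as.integer(input_length)
  for (i in seq_along(channel_widths)) {
    len <- len %/% 2L          # same-padded conv keeps length; pool halves
    lens[i] <- len
  }
  len <- len %/% 2L            # extra pool
  lens[length(lens)] <- len
  if (len < 1L) stop_invalid("input too short for this many pooling layers")
  structure(list(input_length = as.integer(input_length),
                 kernel_size = as.integer(kernel_size),
                 channel_widths = as.integer(channel_widths),
                 final_length = len,
                 fc_in = len * channel_widths[length(channel_widths)]),
            class = "network_spec")
}

# He-normal initialisation of all parameters.
cnn_init <- function(spec = network_spec(), seed = 1L) {
  with_seed(seed, {
    k <- spec$kernel_size
    widths <- spec$channel_widths
    conv <- vector("list", length(widths))
    cin <- 1L
    for (i in seq_along(widths)) {
      cout <- widths[i]
      conv[[i]] <- list(
        W = array(stats::rnorm(k * cin * cout, 0, sqrt(2 / (k * cin))),
                  dim = c(k, cin, cout)),
        b = numeric(cout))
      cin <- cout
    }
    fc <- list(W = matrix(stats::rnorm(spec$fc_in, 0, sqrt(2 / spec$fc_in)),
                          spec$fc_in, 1L),
               b = 0)
    structure(list(spec = spec, conv = conv, fc = fc), class = "cnn_net")
  })
}

# Same-padded 1-D convolution. X: B x L x Cin array; W: k x Cin x Cout.
# Columns of the im2col matrix follow the array's own flattening order
# (kernel offset fastest, then input channel), so matrix(W, k*Cin, Cout)
# lines up.
conv1d_forward <- function(X, W, b) {
  d <- dim(X); B <- d[1]; L <- d[2]; cin <- d[3]
  k <- dim(W)[1]; cout <- dim(W)[3]; p <- (k - 1L) %/% 2L
  Xp <- array(0, c(B, L + 2L * p, cin))
  Xp[, p + seq_len(L), ] <- X
  M <- matrix(0, B * L, k * cin)
  for (c in seq_len(cin)) {
    for (kk in seq_len(k)) {
      M[, (c - 1L) * k + kk] <- Xp[, kk - 1L + seq_len(L), c]
    }
  }
  out <- M %*% matrix(W, k * cin, cout)
  out <- sweep(out, 2, b, "+")
  list(Y = array(out, c(B, L, cout)), M = M)
}

conv1d_backward <- function(dY, M, X_dim, W) {
  B <- X_dim[1]; L <- X_dim[2]; cin <- X_dim[3]
  k <- dim(W)[1]; cout <- dim(W)[3]; p <- (k - 1L) %/% 2L
  dYm <- matrix(dY, B * L, cout)
  dW <- array(crossprod(M, dYm), dim = dim(W))
  db <- colSums(dYm)
  dM <- dYm %*% t(matrix(W, k * cin, cout))
  dXp <- array(0, c(B, L + 2L * p, cin))
  for (c in seq_len(cin)) {
    for (kk in seq_len(k)) {
      dXp[, kk - 1L + seq_len(L), c] <- dXp[, kk - 1L + seq_len(L), c] +
        matrix(dM[, (c - 1L) * k + kk], B, L)
    }
  }
  list(dX = dXp[, p + seq_len(L), , drop = FALSE], dW = dW, db = db)
}

# Max-pool over non-overlapping pairs (stride 2); an odd trailing sample is
# dropped. Ties route the gradient left.
pool_forward <- function(X) {
  L2 <- dim(X)[2] %/% 2L
  odd <- X[, seq(1L, 2L * L2, 2L), , drop = FALSE]
  even <- X[, seq(2L, 2L * L2, 2L), , drop = FALSE]
  list(Y = pmax(odd, even), left = odd >= even, L2 = L2)
}

pool_backward <- function(dY, cache, X_dim) {
  dX <- array(0, X_dim)
  L2 <- cache$L2
  dX[, seq(1L, 2L * L2, 2L), ] <- dY * cache$left
  dX[, seq(2L, 2L * L2, 2L), ] <- dY * !cache$left
  dX
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# Forward pass. X: B x input_length matrix. Returns scores in (0, 1) and,
# optionally, the caches needed for the backward pass.
cnn_forward <- function(net, X, keep_cache = FALSE) {
  B <- nrow(X)
  A <- array(X, c(B, ncol(X), 1L))
  caches <- list()
  for (i in seq_along(net$conv)) {
    cf <- conv1d_forward(A, net$conv[[i]]$W, net$conv[[i]]$b)
    Z <- cf$Y
    R <- Z * (Z > 0)
    pf <- pool_forward(R)
    if (keep_cache) {
      caches[[i]] <- list(X_dim = dim(A), M = cf$M, relu_mask = Z > 0,
                          pool = pf, R_dim = dim(R))
    }
    A <- pf$Y
  }
  pf <- pool_forward(A)          # extra pool
  if (keep_cache) caches$extra <- list(pool = pf, X_dim = dim(A))
  A2 <- pf$Y
  Xf <- matrix(A2, B, length(A2) / B)
  z <- drop(Xf %*% net$fc$W) + net$fc$b
  s <- sigmoid(z)
  if (keep_cache) list(scores = s, caches = caches, Xf = Xf, A2_dim = dim(A2))
  else s
}

# Backward pass from d(loss)/d(score). Returns gradients shaped like the
# parameter list.
cnn_backward <- function(net, fwd, dscore) {
  s <- fwd$scores
  dz <- dscore * s * (1 - s)
  dW_fc <- crossprod(fwd$Xf, matrix(dz, ncol = 1L))
  db_fc <- sum(dz)
  dXf <- matrix(dz, ncol = 1L) %*% t(net$fc$W)
  dA2 <- array(dXf, fwd$A2_dim)
  dA <- pool_backward(dA2, fwd$caches$extra$pool, fwd$caches$extra$X_dim)
  grads <- vector("list", length(net$conv))
  for (i in rev(seq_along(net$conv))) {
    cc <- fwd$caches[[i]]
    dR <- pool_backward(dA, cc$pool, cc$R_dim)
    dZ <- dR * cc$relu_mask
    cb <- conv1d_backward(dZ, cc$M, cc$X_dim, net$conv[[i]]$W)
    grads[[i]] <- list(dW = cb$dW, db = cb$db)
    dA <- cb$dX
  }
  list(conv = grads, fc = list(dW = dW_fc, db = db_fc))
}

adam_init <- function(net) {
  zero_like <- function(p) list(W = array(0, dim(as.array(p$W))), b = p$b * 0)
  list(m = list(conv = lapply(net$conv, zero_like),
                fc = list(W = net$fc$W * 0, b = 0)),
       v = list(conv = lapply(net$conv, zero_like),
                fc = list(W = net$fc$W * 0, b = 0)),
       t = 0L)
}

adam_step <- function(net, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  corr1 <- 1 - beta1^state$t
  corr2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    p <- p - lr * (m / corr1) / (sqrt(v / corr2) + eps)
    list(p = p, m = m, v = v)
  }
  for (i in seq_along(net$conv)) {
    uw <- upd(net$conv[[i]]$W, grads$conv[[i]]$dW,
              state$m$conv[[i]]$W, state$v$conv[[i]]$W)
    ub <- upd(net$conv[[i]]$b, grads$conv[[i]]$db,
              state$m$conv[[i]]$b, state$v$conv[[i]]$b)
    net$conv[[i]]$W <- uw$p; state$m$conv[[i]]$W <- uw$m; state$v$conv[[i]]$W <- uw$v
    net$conv[[i]]$b <- ub$p; state$m$conv[[i]]$b <- ub$m; state$v$conv[[i]]$b <- ub$v
  }
  uw <- upd(net$fc$W, grads$fc$dW, state$m$fc$W, state$v$fc$W)
  ub <- upd(net$fc$b, grads$fc$db, state$m$fc$b, state$v$fc$b)
  net$fc$W <- uw$p; state$m$fc$W <- uw$m; state$v$fc$W <- uw$v
  net$fc$b <- ub$p; state$m$fc$b <- ub$m; state$v$fc$b <- ub$v
  list(net = net, state = state)
}
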