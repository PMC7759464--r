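# A small 1D convolutional network over statistics x subwindow feature
# matrices, written in base R matrix operations: two convolution layers
# (kernel spanning 3 subwindows) with ReLU, a dense hidden layer and a
# softmax output, trained with Adam, minibatches and early stopping on a
# validation split. Sized for feature matrices of 18 statistics x 21
# subwindows; all layer widths are configuration.

relu <- function(x) pmax(x, 0)

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# im2col for an (n, C, L) array with kernel K: returns (n*(L-K+1)) x (C*K)
# with row index (t-1)*n + i and column index (k-1)*C + c.
im2col <- function(X, K) {
  d <- dim(X)
  n <- d[1]; C <- d[2]; L <- d[3]
  Lo <- L - K + 1L
  P <- matrix(0, n * Lo, C * K)
  for (k in seq_len(K)) {
    blk <- aperm(X[, , k:(k + Lo - 1L), drop = FALSE], c(1L, 3L, 2L))
    dim(blk) <- c(n * Lo, C)
    P[, ((k - 1L) * C + 1L):(k * C)] <- blk
  }
  P
}

# transpose of im2col: scatter gradient patches back to an (n, C, L) array
col2im <- function(dP, n, C, L, K) {
  Lo <- L - K + 1L
  dX <- array(0, dim = c(n, C, L))
  for (k in seq_len(K)) {
    blk <- dP[, ((k - 1L) * C + 1L):(k * C), drop = FALSE]
    dim(blk) <- c(n, Lo, C)
    dX[, , k:(k + Lo - 1L)] <- dX[, , k:(k + Lo - 1L), drop = FALSE] +
      aperm(blk, c(1L, 3L, 2L))
  }
  dX
}

cnn_init <- function(C, L, K = 3L, f1 = 16L, f2 = 16L, hidden = 32L,
                     n_classes = 3L) {
  he <- function(nin, nout) {
    matrix(stats::rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  }
  L1 <- L - K + 1L
  L2 <- L1 - K + 1L
  list(W1 = he(C * K, f1), b1 = numeric(f1),
       W2 = he(f1 * K, f2), b2 = numeric(f2),
       W3 = he(f2 * L2, hidden), b3 = numeric(hidden),
       W4 = he(hidden, n_classes), b4 = numeric(n_classes),
       arch = list(C = C, L = L, K = K, f1 = f1, f2 = f2,
                   hidden = hidden, n_classes = n_classes))
}

cnn_forward <- function(par, X, keep = FALSE, dropout = 0) {
  a <- par$arch
  n <- dim(X)[1]
  L1 <- a$L - a$K + 1L
  L2 <- L1 - a$K + 1L
  P1 <- im2col(X, a$K)
  Z1 <- sweep(P1 %*% par$W1, 2L, par$b1, "+")
  A1 <- relu(Z1)                            # (n*L1) x f1
  A1a <- array(0, dim = c(n, a$f1, L1))
  # row (t-1)*n + i -> [i, , t]
  dim(A1) <- c(n, L1, a$f1)
  A1a <- aperm(A1, c(1L, 3L, 2L))
  P2 <- im2col(A1a, a$K)
  Z2 <- sweep(P2 %*% par$W2, 2L, par$b2, "+")
  A2 <- relu(Z2)                            # (n*L2) x f2
  dim(A2) <- c(n, L2, a$f2)
  A2a <- aperm(A2, c(1L, 3L, 2L))
  flat <- matrix(A2a, n, a$f2 * L2)
  Z3 <- sweep(flat %*% par$W3, 2L, par$b3, "+")
  A3 <- relu(Z3)
  dmask <- NULL
  if (dropout > 0) {
    dmask <- matrix(stats::runif(length(A3)) >= dropout,
                    nrow(A3), ncol(A3)) / (1 - dropout)
    A3 <- A3 * dmask
  }
  Z4 <- sweep(A3 %*% par$W4, 2L, par$b4, "+")
  probs <- softmax_rows(Z4)
  if (!keep) return(probs)
  list(probs = probs, P1 = P1, Z1 = Z1, A1a = A1a, P2 = P2, Z2 = Z2,
       A2a = A2a, flat = flat, Z3 = Z3, A3 = A3, dmask = dmask)
}

cnn_backward <- function(par, X, Y, cache, weight_decay = 1e-4) {
  a <- par$arch
  n <- dim(X)[1]
  L1 <- a$L - a$K + 1L
  L2 <- L1 - a$K + 1L
  dZ4 <- (cache$probs - Y) / n
  gW4 <- t(cache$A3) %*% dZ4 + weight_decay * par$W4
  gb4 <- colSums(dZ4)
  dA3 <- dZ4 %*% t(par$W4)
  if (!is.null(cache$dmask)) dA3 <- dA3 * cache$dmask
  dZ3 <- dA3 * (cache$Z3 > 0)
  gW3 <- t(cache$flat) %*% dZ3 + weight_decay * par$W3
  gb3 <- colSums(dZ3)
  dflat <- dZ3 %*% t(par$W3)                 # n x (f2*L2)
  dA2a <- array(dflat, dim = c(n, a$f2, L2))
  dA2 <- aperm(dA2a, c(1L, 3L, 2L))          # n x L2 x f2
  dim(dA2) <- c(n * L2, a$f2)
  dZ2 <- dA2 * (cache$Z2 > 0)
  gW2 <- t(cache$P2) %*% dZ2 + weight_decay * par$W2
  gb2 <- colSums(dZ2)
  dP2 <- dZ2 %*% t(par$W2)
  dA1a <- col2im(dP2, n, a$f1, L1, a$K)
  dA1 <- aperm(dA1a, c(1L, 3L, 2L))          # n x L1 x f1
  dim(dA1) <- c(n * L1, a$f1)
  dZ1 <- dA1 * (cache$Z1 > 0)
  gW1 <- t(cache$P1) %*% dZ1 + weight_decay * par$W1
  gb1 <- colSums(dZ1)
  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2, W3 = gW3, b3 = gb3,
       W4 = gW4, b4 = gb4)
}

cross_entropy <- function(probs, Y) {
  -mean(rowSums(Y * log(pmax(probs, 1e-12))))
}

adam_init <- function(par) {
  nm <- c("W1", "b1", "W2", "b2", "W3", "b3", "W4", "b4")
  list(m = lapply(par[nm], function(x) x * 0),
       v = lapply(par[nm], function(x) x * 0), t = 0L)
}

adam_step <- function(par, grads, st, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  st$t <- st$t + 1L
  for (nm in names(st$m)) {
    st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * grads[[nm]]
    st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- st$m[[nm]] / (1 - beta1^st$t)
    vhat <- st$v[[nm]] / (1 - beta2^st$t)
    par[[nm]] <- par[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(par = par, st = st)
}

onehot <- function(y, n_classes) {
  Y <- matrix(0, length(y), n_classes)
  Y[cbind(seq_along(y), as.integer(y))] <- 1
  Y
}
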