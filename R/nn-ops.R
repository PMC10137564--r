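# Low-level differentiable ops for the segmentation network.
#
# Tensors are numeric arrays dim = c(H, W, C, N). Convolutions run through
# compiled im2col/col2im kernels with the matrix product done by BLAS. Each
# *_f() returns list(y, cache); each *_b() consumes the upstream gradient and
# the cache and returns input/parameter gradients. Correctness of every
# backward pass is pinned by finite-difference tests.

conv_init <- function(k, cin, cout, zero = FALSE) {
  w <- if (zero) rep(0, k * k * cin * cout) else
    rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin)))
  list(W = matrix(w, k * k * cin, cout), b = rep(0, cout))
}

conv_f <- function(x, par, k, stride = 1L, pad = (k - 1L) %/% 2L) {
  d <- dim(x)
  cols <- im2col_hw(x, d[1], d[2], d[3], d[4], k, stride, pad)
  y <- cols %*% par$W
  y <- sweep_add_bias(y, par$b)
  Ho <- (d[1] + 2 * pad - k) %/% stride + 1L
  Wo <- (d[2] + 2 * pad - k) %/% stride + 1L
  cout <- ncol(par$W)
  y <- aperm(array(y, c(Ho, Wo, d[4], cout)), c(1, 2, 4, 3))
  list(y = y, cache = list(x = x, k = k, stride = stride, pad = pad,
                           dims = d, odims = c(Ho, Wo, cout, d[4])))
}

sweep_add_bias <- function(y, b) {
  if (all(b == 0)) return(y)
  y + rep(b, each = nrow(y))
}

conv_b <- function(dy, par, cache) {
  d <- cache$dims; od <- cache$odims
  dymat <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = od[3])
  cols <- im2col_hw(cache$x, d[1], d[2], d[3], d[4],
                    cache$k, cache$stride, cache$pad)
  dW <- crossprod(cols, dymat)
  db <- colSums(dymat)
  dcols <- dymat %*% t(par$W)
  dx <- col2im_hw(dcols, d[1], d[2], d[3], d[4],
                  cache$k, cache$stride, cache$pad)
  list(dx = dx, dW = dW, db = db)
}

bn_init <- function(c) {
  list(gamma = rep(1, c), beta = rep(0, c),
       run_mean = rep(0, c), run_var = rep(1, c))
}

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1

bn_f <- function(x, par, training) {
  d <- dim(x)
  C <- d[3]
  M <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)  # (H*W*N) x C
  m <- nrow(M)
  if (training) {
    mu <- colMeans(M)
    xc <- M - rep(mu, each = m)
    v <- colMeans(xc * xc)
    run_mean <- (1 - BN_MOMENTUM) * par$run_mean + BN_MOMENTUM * mu
    run_var <- (1 - BN_MOMENTUM) * par$run_var +
      BN_MOMENTUM * v * m / max(m - 1, 1)
  } else {
    mu <- par$run_mean
    v <- par$run_var
    xc <- M - rep(mu, each = m)
    run_mean <- par$run_mean
    run_var <- par$run_var
  }
  invstd <- 1 / sqrt(v + BN_EPS)
  xhat <- xc * rep(invstd, each = m)
  Y <- xhat * rep(par$gamma, each = m) + rep(par$beta, each = m)
  y <- aperm(array(Y, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(y = y,
       cache = list(xhat = xhat, invstd = invstd, dims = d, training = training),
       run_mean = run_mean, run_var = run_var)
}

bn_b <- function(dy, par, cache) {
  d <- cache$dims; C <- d[3]
  dY <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
  m <- nrow(dY)
  xhat <- cache$xhat
  dgamma <- colSums(dY * xhat)
  dbeta <- colSums(dY)
  dxhat <- dY * rep(par$gamma, each = m)
  if (cache$training) {
    s1 <- colSums(dxhat)
    s2 <- dgamma  # = colSums(dxhat * xhat) / gamma ... recompute exactly:
    s2 <- colSums(dxhat * xhat)
    dX <- (dxhat - rep(s1 / m, each = m) - xhat * rep(s2 / m, each = m)) *
      rep(cache$invstd, each = m)
  } else {
    dX <- dxhat * rep(cache$invstd, each = m)
  }
  dx <- aperm(array(dX, c(d[1], d[2], d[4], d[3])), c(1, 2, 4, 3))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

relu_f <- function(x) {
  mask <- x > 0
  list(y = x * mask, cache = mask)
}

relu_b <- function(dy, mask) dy * mask

pool_f <- function(x) {
  d <- dim(x)
  r <- maxpool2_fwd(x, d[1], d[2], d[3], d[4])
  list(y = r$out, cache = list(idx = r$idx, dims = d))
}

pool_b <- function(dy, cache) {
  d <- cache$dims
  maxpool2_bwd(dy, cache$idx, d[1], d[2], d[3], d[4])
}

upsample_f <- function(x) {
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2), rep(seq_len(d[2]), each = 2), , , drop = FALSE]
  list(y = y, cache = d)
}

upsample_b <- function(dy, d) {
  r <- seq(1, 2 * d[1], by = 2); cc <- seq(1, 2 * d[2], by = 2)
  dy[r, cc, , , drop = FALSE] + dy[r + 1, cc, , , drop = FALSE] +
    dy[r, cc + 1, , , drop = FALSE] + dy[r + 1, cc + 1, , , drop = FALSE]
}

concat_f <- function(a, b) {
  da <- dim(a); db <- dim(b)
  y <- array(0, c(da[1], da[2], da[3] + db[3], da[4]))
  y[, , seq_len(da[3]), ] <- a
  y[, , da[3] + seq_len(db[3]), ] <- b
  list(y = y, cache = c(da[3], db[3]))
}

concat_b <- function(dy, split) {
  list(da = dy[, , seq_len(split[1]), , drop = FALSE],
       db = dy[, , split[1] + seq_len(split[2]), , drop = FALSE])
}

# Per-pixel softmax over the class dimension; works on the (pixels x classes)
# matrix view used by the loss.
softmax_rows <- function(M) {
  mx <- M[, 1]
  for (j in seq_len(ncol(M))[-1]) mx <- pmax(mx, M[, j])
  E <- exp(M - mx)
  E / rowSums(E)
}
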