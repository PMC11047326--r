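# Dense tensor primitives for the embedding network.
#
# Tensor layout is channel-first (C, H, W, N): a spatial slice of a padded
# tensor then flattens directly into the C x (H'*W'*N) matrix that BLAS wants,
# so a k x k convolution is k^2 shifted matrix products. Each forward returns
# the cache its backward needs; all gradients are exact and are checked against
# central finite differences in the test suite.

conv2d_init <- function(c_in, c_out, k, gain = sqrt(2)) {
  # He-style fan-in scaling
  sd <- gain / sqrt(c_in * k * k)
  array(stats::rnorm(c_out * c_in * k * k, sd = sd), c(c_out, c_in, k, k))
}

# Memoized gather/scatter index vectors per (input dims, k, stride, pad):
# shapes are fixed per layer, so these are computed once per run.
.conv_idx_cache <- new.env(parent = emptyenv())

conv_indices <- function(d, k, stride, pad) {
  key <- paste(c(d, k, stride, pad), collapse = "_")
  hit <- .conv_idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  H <- d[2L]; Wd <- d[3L]; N <- d[4L]
  Hp <- H + 2L * pad; Wp <- Wd + 2L * pad
  Ho <- (Hp - k) %/% stride + 1L
  Wo <- (Wp - k) %/% stride + 1L
  noff <- rep(Hp * Wp * (seq_len(N) - 1L), each = Ho * Wo)
  tap <- vector("list", k * k)
  for (kx in seq_len(k)) {
    for (ky in seq_len(k)) {
      hv <- ky + (seq_len(Ho) - 1L) * stride
      wv <- kx + (seq_len(Wo) - 1L) * stride
      hw <- rep(hv - 1L, times = Wo) + rep(Hp * (wv - 1L), each = Ho)
      tap[[(kx - 1L) * k + ky]] <- rep(hw, times = N) + noff + 1L
    }
  }
  # interior (unpadded) cells of the padded tensor, in input storage order
  hw_in <- rep(pad + seq_len(H) - 1L, times = Wd) +
    rep(Hp * (pad + seq_len(Wd) - 1L), each = H)
  inner <- rep(hw_in, times = N) + rep(Hp * Wp * (seq_len(N) - 1L), each = H * Wd) + 1L
  res <- list(tap = tap, inner = inner, Hp = Hp, Wp = Wp, Ho = Ho, Wo = Wo)
  .conv_idx_cache[[key]] <- res
  res
}

conv2d_fwd <- function(x, W, b = NULL, stride = 1L, pad = 1L) {
  d <- dim(x)
  c_in <- d[1L]; N <- d[4L]
  k <- dim(W)[3L]; c_out <- dim(W)[1L]
  ci <- conv_indices(d, k, stride, pad)
  if (pad > 0L) {
    xpm <- matrix(0, c_in, ci$Hp * ci$Wp * N)
    xpm[, ci$inner] <- x
  } else {
    xpm <- matrix(x, c_in)
  }
  P <- ci$Ho * ci$Wo * N
  cols_mat <- matrix(0, c_in * k * k, P)
  for (tt in seq_len(k * k)) {
    cols_mat[(tt - 1L) * c_in + seq_len(c_in), ] <- xpm[, ci$tap[[tt]]]
  }
  out <- matrix(W, c_out) %*% cols_mat
  if (!is.null(b)) out <- out + b
  list(y = array(out, c(c_out, ci$Ho, ci$Wo, N)),
       cache = list(cols_mat = cols_mat, dimx = d, stride = stride,
                    pad = pad, k = k, ci = ci))
}

conv2d_bwd <- function(dy, cache, W, has_bias = FALSE) {
  d <- cache$dimx
  c_in <- d[1L]; N <- d[4L]
  k <- cache$k; ci <- cache$ci
  c_out <- dim(W)[1L]
  dyM <- matrix(dy, c_out)
  dW <- array(tcrossprod(dyM, cache$cols_mat), dim(W))
  dcols <- crossprod(matrix(W, c_out), dyM)        # (c_in*k*k) x P
  dxpm <- matrix(0, c_in, ci$Hp * ci$Wp * N)
  for (tt in seq_len(k * k)) {
    idx <- ci$tap[[tt]]
    dxpm[, idx] <- dxpm[, idx] + dcols[(tt - 1L) * c_in + seq_len(c_in), ]
  }
  dx <- if (cache$pad > 0L) dxpm[, ci$inner, drop = FALSE] else dxpm
  out <- list(dx = array(dx, d), dW = dW)
  if (has_bias) out$db <- rowSums(dyM)
  out
}

bn_fwd <- function(x, gamma, beta, rmean, rvar, training,
                   momentum = 0.1, eps = 1e-5) {
  d <- dim(x)
  C <- d[1L]
  xm <- matrix(x, C)
  if (training) {
    mu <- rowMeans(xm)
    xc <- xm - mu
    v <- rowMeans(xc * xc)
    rmean <- (1 - momentum) * rmean + momentum * mu
    rvar <- (1 - momentum) * rvar + momentum * v
  } else {
    mu <- rmean
    v <- rvar
    xc <- xm - mu
  }
  inv <- 1 / sqrt(v + eps)
  xh <- xc * inv
  list(y = array(gamma * xh + beta, d),
       cache = list(xh = xh, inv = inv, d = d, training = training),
       rmean = rmean, rvar = rvar)
}

bn_bwd <- function(dy, cache, gamma) {
  d <- cache$d
  dyM <- matrix(dy, d[1L])
  xh <- cache$xh
  dgamma <- rowSums(dyM * xh)
  dbeta <- rowSums(dyM)
  if (cache$training) {
    dxh <- dyM * gamma
    dx <- cache$inv * (dxh - rowMeans(dxh) - xh * rowMeans(dxh * xh))
  } else {
    dx <- dyM * gamma * cache$inv
  }
  list(dx = array(dx, d), dgamma = dgamma, dbeta = dbeta)
}

relu_fwd <- function(x) {
  m <- x > 0
  list(y = x * m, cache = m)
}

relu_bwd <- function(dy, mask) dy * mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# Global average pooling (C,H,W,N) -> (C,N)
gap_fwd <- function(x) {
  d <- dim(x)
  xr <- x
  dim(xr) <- c(d[1L], d[2L] * d[3L], d[4L])
  y <- matrix(apply(xr, 3L, rowMeans), d[1L], d[4L])
  list(y = y, cache = d)
}

gap_bwd <- function(dy, d) {
  P <- d[2L] * d[3L]
  dx <- aperm(array(dy / P, c(d[1L], d[4L], P)), c(1L, 3L, 2L))
  dim(dx) <- d
  dx
}

# Global max pooling with argmax tracking, (C,H,W,N) -> (C,N)
gmp_fwd <- function(x) {
  d <- dim(x)
  C <- d[1L]; P <- d[2L] * d[3L]; N <- d[4L]
  xr <- x
  dim(xr) <- c(C, P, N)
  y <- matrix(0, C, N)
  idx <- matrix(1L, C, N)
  for (n in seq_len(N)) {
    xm <- matrix(xr[, , n], C, P)
    mx <- xm[, 1L]
    im <- rep(1L, C)
    for (p in seq_len(P)[-1L]) {
      better <- xm[, p] > mx
      mx[better] <- xm[better, p]
      im[better] <- p
    }
    y[, n] <- mx
    idx[, n] <- im
  }
  list(y = y, cache = list(d = d, idx = idx))
}

gmp_bwd <- function(dy, cache) {
  d <- cache$d
  C <- d[1L]; P <- d[2L] * d[3L]; N <- d[4L]
  dx <- array(0, c(C, P, N))
  for (n in seq_len(N)) {
    dx[cbind(seq_len(C), cache$idx[, n], n)] <- dy[, n]
  }
  dim(dx) <- d
  dx
}

linear_init <- function(n_in, n_out, sd = NULL) {
  if (is.null(sd)) sd <- 1 / sqrt(n_in)
  matrix(stats::rnorm(n_out * n_in, sd = sd), n_out, n_in)
}

linear_fwd <- function(x, W, b) {
  list(y = W %*% x + b, cache = x)
}

linear_bwd <- function(dy, x, W) {
  list(dx = crossprod(W, dy), dW = tcrossprod(dy, x), db = rowSums(dy))
}

# Broadcast a (C,N) per-channel value over spatial positions -> (C,H,W,N)
bc_channel <- function(g, d) {
  P <- d[2L] * d[3L]
  out <- aperm(array(g, c(d[1L], d[4L], P)), c(1L, 3L, 2L))
  dim(out) <- d
  out
}

# Sum a (C,H,W,N) tensor over spatial positions -> (C,N)
sum_spatial <- function(x) {
  d <- dim(x)
  xr <- x
  dim(xr) <- c(d[1L], d[2L] * d[3L], d[4L])
  matrix(apply(xr, 3L, rowSums), d[1L], d[4L])
}
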