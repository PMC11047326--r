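# Spatial transformer: localization network -> affine grid -> bilinear sampler.
#
# Conventions. theta is the 2x3 affine matrix mapping *target* to *source*
# coordinates: (x_s, y_s)' = theta %*% (x_t, y_t, 1)'. Coordinates are
# normalized to [-1, 1] with -1/+1 at the centers of the first/last pixel
# (align-corners), so the identity theta reproduces the input exactly.
# Sampling outside the source extent reads zeros.

#' Affine sampling grid from transformation parameters
#'
#' Builds the source-coordinate sampling grid for a target feature map of the
#' given shape: for every target pixel, the source location is
#' `theta %*% c(x_t, y_t, 1)` in normalized `[-1, 1]` coordinates.
#'
#' @param theta 2x3 numeric affine matrix (rows: x and y source coordinates).
#' @param out_shape integer vector `c(H, W)` of the target grid.
#' @return An `H x W x 2` array; `[, , 1]` holds `x_s`, `[, , 2]` holds `y_s`.
#' @examples
#' g <- grid_generator(cbind(diag(2), 0), c(4, 4))
#' g[1, 1, ] # top-left target pixel maps to (-1, -1)
#' @export
grid_generator <- function(theta, out_shape) {
  stopifnot(is.matrix(theta), all(dim(theta) == c(2L, 3L)),
            length(out_shape) == 2L, all(out_shape >= 1L))
  H <- out_shape[1L]; W <- out_shape[2L]
  xt <- if (W == 1L) 0 else seq(-1, 1, length.out = W)
  yt <- if (H == 1L) 0 else seq(-1, 1, length.out = H)
  XT <- matrix(xt, H, W, byrow = TRUE)
  YT <- matrix(yt, H, W)
  grid <- array(0, c(H, W, 2L))
  grid[, , 1L] <- theta[1L, 1L] * XT + theta[1L, 2L] * YT + theta[1L, 3L]
  grid[, , 2L] <- theta[2L, 1L] * XT + theta[2L, 2L] * YT + theta[2L, 3L]
  grid
}

# Batched grid: theta (6,N) rows (t11,t12,t13,t21,t22,t23) -> (H,W,2,N).
grid_generator_batch <- function(theta, out_shape) {
  H <- out_shape[1L]; W <- out_shape[2L]
  N <- ncol(theta)
  xt <- if (W == 1L) 0 else seq(-1, 1, length.out = W)
  yt <- if (H == 1L) 0 else seq(-1, 1, length.out = H)
  XT <- matrix(xt, H, W, byrow = TRUE)
  YT <- matrix(yt, H, W)
  grid <- array(0, c(H, W, 2L, N))
  for (n in seq_len(N)) {
    grid[, , 1L, n] <- theta[1L, n] * XT + theta[2L, n] * YT + theta[3L, n]
    grid[, , 2L, n] <- theta[4L, n] * XT + theta[5L, n] * YT + theta[6L, n]
  }
  list(grid = grid, XT = XT, YT = YT)
}

# Gradient of the batched grid wrt theta: dgrid (H,W,2,N) -> (6,N).
grid_generator_batch_bwd <- function(dgrid, XT, YT) {
  N <- dim(dgrid)[4L]
  dtheta <- matrix(0, 6L, N)
  for (n in seq_len(N)) {
    dgx <- dgrid[, , 1L, n]
    dgy <- dgrid[, , 2L, n]
    dtheta[, n] <- c(sum(dgx * XT), sum(dgx * YT), sum(dgx),
                     sum(dgy * XT), sum(dgy * YT), sum(dgy))
  }
  dtheta
}

# Batched bilinear sampler. x (C,H,W,N), grid (Ho,Wo,2,N) -> (C,Ho,Wo,N).
bilinear_fwd <- function(x, grid) {
  d <- dim(x)
  C <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  gd <- dim(grid)
  Ho <- gd[1L]; Wo <- gd[2L]
  stopifnot(gd[4L] == N)
  gx <- as.vector(grid[, , 1L, ])
  gy <- as.vector(grid[, , 2L, ])
  P <- Ho * Wo * N
  nn <- rep(seq_len(N), each = Ho * Wo)
  ix <- (gx + 1) / 2 * (W - 1) + 1
  iy <- (gy + 1) / 2 * (H - 1) + 1
  x0 <- floor(ix); y0 <- floor(iy)
  wx <- ix - x0; wy <- iy - y0
  xmat <- matrix(x, C)
  gather <- function(hh, ww) {
    valid <- hh >= 1 & hh <= H & ww >= 1 & ww <= W
    col <- (hh - 1) + H * (ww - 1) + H * W * (nn - 1) + 1
    col[!valid] <- 1
    G <- xmat[, col, drop = FALSE]
    if (!all(valid)) G[, !valid] <- 0
    list(G = G, col = col, valid = valid)
  }
  s00 <- gather(y0, x0)
  s01 <- gather(y0, x0 + 1)
  s10 <- gather(y0 + 1, x0)
  s11 <- gather(y0 + 1, x0 + 1)
  w00 <- (1 - wy) * (1 - wx); w01 <- (1 - wy) * wx
  w10 <- wy * (1 - wx);       w11 <- wy * wx
  yM <- s00$G * rep(w00, each = C) + s01$G * rep(w01, each = C) +
        s10$G * rep(w10, each = C) + s11$G * rep(w11, each = C)
  list(y = array(yM, c(C, Ho, Wo, N)),
       cache = list(d = d, gdim = gd, s00 = s00, s01 = s01, s10 = s10,
                    s11 = s11, wx = wx, wy = wy, P = P))
}

bilinear_bwd <- function(dy, cache) {
  d <- cache$d
  C <- d[1L]; H <- d[2L]; W <- d[3L]; N <- d[4L]
  wx <- cache$wx; wy <- cache$wy
  dyM <- matrix(dy, C)
  dxmat <- matrix(0, C, H * W * N)
  acc <- function(dxmat, s, w) {
    keep <- s$valid & w != 0
    if (!any(keep)) return(dxmat)
    contrib <- dyM[, keep, drop = FALSE] * rep(w[keep], each = C)
    agg <- rowsum(t(contrib), group = s$col[keep])
    ucols <- as.integer(rownames(agg))
    dxmat[, ucols] <- dxmat[, ucols] + t(agg)
    dxmat
  }
  w00 <- (1 - wy) * (1 - wx); w01 <- (1 - wy) * wx
  w10 <- wy * (1 - wx);       w11 <- wy * wx
  dxmat <- acc(dxmat, cache$s00, w00)
  dxmat <- acc(dxmat, cache$s01, w01)
  dxmat <- acc(dxmat, cache$s10, w10)
  dxmat <- acc(dxmat, cache$s11, w11)
  # grid gradient: d(out)/d(ix) and d(out)/d(iy), summed over channels
  dix <- colSums(dyM * ((cache$s01$G - cache$s00$G) * rep(1 - wy, each = C) +
                        (cache$s11$G - cache$s10$G) * rep(wy, each = C)))
  diy <- colSums(dyM * ((cache$s10$G - cache$s00$G) * rep(1 - wx, each = C) +
                        (cache$s11$G - cache$s01$G) * rep(wx, each = C)))
  dgx <- dix * (W - 1) / 2
  dgy <- diy * (H - 1) / 2
  gd <- cache$gdim
  dgrid <- array(0, gd)
  dgrid[, , 1L, ] <- array(dgx, c(gd[1L], gd[2L], gd[4L]))
  dgrid[, , 2L, ] <- array(dgy, c(gd[1L], gd[2L], gd[4L]))
  list(dx = array(dxmat, d), dgrid = dgrid)
}

#' Bilinear sampling of a feature map at a sampling grid
#'
#' Samples a single feature map at the normalized source coordinates of
#' `grid`, interpolating bilinearly between the four nearest source pixels;
#' coordinates outside `[-1, 1]` read zeros.
#'
#' @param f `C x H x W` numeric array (a single feature map). A plain `H x W`
#'   matrix is treated as one channel.
#' @param grid `Ho x Wo x 2` array of normalized source coordinates, as
#'   produced by [grid_generator()].
#' @return `C x Ho x Wo` array.
#' @export
bilinear_sample <- function(f, grid) {
  if (is.matrix(f)) f <- array(f, c(1L, dim(f)))
  stopifnot(length(dim(f)) == 3L, length(dim(grid)) == 3L,
            dim(grid)[3L] == 2L)
  xb <- array(f, c(dim(f), 1L))
  gb <- array(grid, c(dim(grid), 1L))
  out <- bilinear_fwd(xb, gb)$y
  array(out, dim(out)[1:3])
}

#' Construct a spatial transformer module
#'
#' The localization network is global average pooling over the feature map
#' followed by two fully connected layers (`channels -> hidden -> 6`). The
#' final layer is zero-initialized with an identity bias, so an untrained
#' module predicts exactly the identity transform and the whole transformer is
#' a numerical no-op until trained.
#'
#' @param channels number of input feature-map channels.
#' @param hidden width of the localization hidden layer.
#' @return An object of class `cowreid_stn`.
#' @export
new_stn <- function(channels, hidden = 64L) {
  layer <- list(
    kind = "stn",
    cfg = list(channels = channels, hidden = hidden),
    par = list(
      W1 = linear_init(channels, hidden),
      b1 = numeric(hidden),
      W2 = matrix(0, 6L, hidden),            # zero init: identity transform
      b2 = c(1, 0, 0, 0, 1, 0)
    )
  )
  class(layer) <- c("cowreid_stn", "cowreid_layer")
  layer
}

#' Predict affine transformation parameters from a feature map
#'
#' Runs the localization network of a spatial transformer on one feature map
#' and returns the 2x3 affine parameter matrix. For an untrained module this
#' is exactly the identity transform.
#'
#' @param stn module from [new_stn()].
#' @param f `C x H x W` feature map.
#' @return 2x3 numeric matrix theta.
#' @export
localization <- function(stn, f) {
  if (is.matrix(f)) f <- array(f, c(1L, dim(f)))
  stopifnot(length(dim(f)) == 3L, dim(f)[1L] == stn$cfg$channels)
  if (any(!is.finite(f))) stop("non-finite activations in localization input")
  g <- matrix(rowMeans(matrix(f, dim(f)[1L])), ncol = 1L)
  h <- pmax(stn$par$W1 %*% g + stn$par$b1, 0)
  th <- stn$par$W2 %*% h + stn$par$b2
  matrix(th, 2L, 3L, byrow = TRUE)
}

#' Apply a spatial transformer to a feature map
#'
#' Composition `bilinear_sample(f, grid_generator(localization(f), dim(f)))`;
#' output shape equals input shape.
#'
#' @inheritParams localization
#' @return Transformed `C x H x W` feature map.
#' @export
stn_transform <- function(stn, f) {
  if (is.matrix(f)) f <- array(f, c(1L, dim(f)))
  theta <- localization(stn, f)
  grid <- grid_generator(theta, dim(f)[2:3])
  bilinear_sample(f, grid)
}

# Batched STN forward/backward used inside the network.
stn_layer_fwd <- function(layer, x, training = TRUE) {
  d <- dim(x)
  gp <- gap_fwd(x)
  l1 <- linear_fwd(gp$y, layer$par$W1, layer$par$b1)
  r1 <- relu_fwd(l1$y)
  l2 <- linear_fwd(r1$y, layer$par$W2, layer$par$b2)
  gg <- grid_generator_batch(l2$y, d[2:3])
  bs <- bilinear_fwd(x, gg$grid)
  list(y = bs$y, layer = layer,
       cache = list(d = d, gp = gp, l1 = l1, r1 = r1, l2 = l2, gg = gg,
                    bs = bs))
}

stn_layer_bwd <- function(layer, dy, cache) {
  bb <- bilinear_bwd(dy, cache$bs$cache)
  dtheta <- grid_generator_batch_bwd(bb$dgrid, cache$gg$XT, cache$gg$YT)
  b2 <- linear_bwd(dtheta, cache$l2$cache, layer$par$W2)
  dr1 <- relu_bwd(b2$dx, cache$r1$cache)
  b1 <- linear_bwd(dr1, cache$l1$cache, layer$par$W1)
  dx_loc <- gap_bwd(b1$dx, cache$gp$cache)
  list(dx = bb$dx + dx_loc,
       grads = list(W1 = b1$dW, b1 = b1$db, W2 = b2$dW, b2 = b2$db))
}
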