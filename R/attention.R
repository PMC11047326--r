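# Attention modules inserted at the end of stage-3/4 residual blocks.
#
# CBAM: channel gate (shared MLP over global avg- and max-pooled descriptors,
# sigmoid) followed by a spatial gate (7x7 conv over the channel-wise mean and
# max maps, sigmoid). SimAM: parameter-free energy-based reweighting from the
# per-channel spatial mean and variance. ParNet SSE: skip squeeze-excitation,
# a single fully connected channel gate. All preserve shape.

#' Construct a learnable attention module
#'
#' @param kind one of `"cbam"`, `"parnet"`, `"simam"`. SimAM has no learnable
#'   parameters; the constructor exists so all three share an interface.
#' @param channels number of feature-map channels the module will see.
#' @param reduction channel reduction ratio of the CBAM shared MLP.
#' @param lambda SimAM stability constant added to the spatial variance.
#' @return An object of class `cowreid_attention`.
#' @export
new_attention <- function(kind = c("cbam", "parnet", "simam"), channels,
                          reduction = 8L, lambda = 1e-4) {
  kind <- match.arg(kind)
  cr <- max(1L, channels %/% reduction)
  par <- switch(kind,
    cbam = list(
      W1 = linear_init(channels, cr), b1 = numeric(cr),
      W2 = linear_init(cr, channels), b2 = numeric(channels),
      Ws = conv2d_init(2L, 1L, 7L, gain = 1), bs = 0
    ),
    parnet = list(W = linear_init(channels, channels), b = numeric(channels)),
    simam = list()
  )
  layer <- list(kind = paste0("att_", kind),
                cfg = list(channels = channels, reduction = cr,
                           lambda = lambda),
                par = par)
  class(layer) <- c("cowreid_attention", "cowreid_layer")
  layer
}

#' Number of learnable parameters of a module
#'
#' @param layer a layer object (attention module, STN, or whole model).
#' @return integer count of learnable scalars.
#' @export
n_parameters <- function(layer) {
  n <- sum(vapply(layer$par, length, integer(1)))
  if (!is.null(layer$sub)) n <- n + sum(vapply(layer$sub, n_parameters, numeric(1)))
  if (!is.null(layer$layers)) n <- n + sum(vapply(layer$layers, n_parameters, numeric(1)))
  if (!is.null(layer$head)) n <- n + length(layer$head)
  n
}

## ---- SimAM ----------------------------------------------------------------

simam_fwd <- function(x, lambda = 1e-4) {
  d <- dim(x)
  C <- d[1L]; P <- d[2L] * d[3L]; N <- d[4L]
  if (P < 2L) stop("SimAM requires at least 2 spatial positions (variance undefined)")
  A <- matrix(aperm(array(x, c(C, P, N)), c(2L, 1L, 3L)), P)  # P x (C*N)
  mu <- colMeans(A)
  cen <- A - rep(mu, each = P)
  dsq <- cen * cen
  v <- colSums(dsq) / (P - 1)
  denom <- 4 * (v + lambda)
  einv <- dsq / rep(denom, each = P) + 0.5
  G <- sigmoid(einv)
  Y <- A * G
  y <- array(aperm(array(Y, c(P, C, N)), c(2L, 1L, 3L)), d)
  list(y = y, cache = list(d = d, A = A, cen = cen, dsq = dsq, v = v,
                           denom = denom, G = G, lambda = lambda))
}

simam_bwd <- function(dy, cache) {
  d <- cache$d
  C <- d[1L]; P <- d[2L] * d[3L]; N <- d[4L]
  g <- matrix(aperm(array(dy, c(C, P, N)), c(2L, 1L, 3L)), P)
  G <- cache$G
  A <- cache$A
  sp <- G * (1 - G)
  a <- g * A * sp                               # dL/d(einv)
  dv <- colSums(a * (-cache$dsq)) * 4 / (cache$denom^2)
  dd <- a / rep(cache$denom, each = P) + rep(dv / (P - 1), each = P)
  dA <- g * G + 2 * dd * cache$cen
  dmu <- colSums(-2 * dd * cache$cen)
  dA <- dA + rep(dmu / P, each = P)
  array(aperm(array(dA, c(P, C, N)), c(2L, 1L, 3L)), d)
}

## ---- CBAM -----------------------------------------------------------------

cbam_fwd <- function(layer, x, training = TRUE) {
  d <- dim(x)
  C <- d[1L]
  p <- layer$par
  ga <- gap_fwd(x)
  gm <- gmp_fwd(x)
  a1 <- linear_fwd(ga$y, p$W1, p$b1); ar <- relu_fwd(a1$y)
  a2 <- linear_fwd(ar$y, p$W2, p$b2)
  m1 <- linear_fwd(gm$y, p$W1, p$b1); mr <- relu_fwd(m1$y)
  m2 <- linear_fwd(mr$y, p$W2, p$b2)
  gc <- sigmoid(a2$y + m2$y)                    # (C,N) channel gate
  x1 <- x * bc_channel(gc, d)
  # spatial gate over channel-wise mean and max of the channel-refined map
  x1m <- matrix(x1, C)
  smean <- colMeans(x1m)
  smax <- x1m[1L, ]
  amax <- rep(1L, length(smax))
  if (C > 1L) for (cc in 2:C) {
    better <- x1m[cc, ] > smax
    smax[better] <- x1m[cc, better]
    amax[better] <- cc
  }
  sin2 <- array(rbind(smean, smax), c(2L, d[2L], d[3L], d[4L]))
  sc_conv <- conv2d_fwd(sin2, p$Ws, p$bs, stride = 1L, pad = 3L)
  gs <- sigmoid(sc_conv$y)                      # (1,H,W,N) spatial gate
  gsv <- as.vector(gs)
  y <- array(matrix(x1, C) * rep(gsv, each = C), d)
  list(y = y, layer = layer,
       cache = list(d = d, ga = ga, gm = gm, a1 = a1, ar = ar, a2 = a2,
                    m1 = m1, mr = mr, m2 = m2, gc = gc, x = x, x1 = x1,
                    amax = amax, sc_conv = sc_conv, gs = gsv))
}

cbam_bwd <- function(layer, dy, cache) {
  d <- cache$d
  C <- d[1L]
  p <- layer$par
  dyM <- matrix(dy, C)
  x1m <- matrix(cache$x1, C)
  gsv <- cache$gs
  # through y = x1 * gs
  dx1 <- dyM * rep(gsv, each = C)
  dgs <- colSums(dyM * x1m)
  # through spatial gate
  dpre <- dgs * gsv * (1 - gsv)
  dpre <- array(dpre, c(1L, d[2L], d[3L], d[4L]))
  cb <- conv2d_bwd(dpre, cache$sc_conv$cache, p$Ws, has_bias = TRUE)
  dsin <- matrix(cb$dx, 2L)                     # rows: mean, max
  # mean map spreads evenly over channels; max map routes to argmax channel
  dx1 <- dx1 + matrix(rep(dsin[1L, ] / C, each = C), C)
  idx <- cbind(cache$amax, seq_along(cache$amax))
  dmax <- matrix(0, C, ncol(x1m))
  dmax[idx] <- dsin[2L, ]
  dx1 <- dx1 + dmax
  # through x1 = x * gc
  xm <- matrix(cache$x, C)
  dx <- array(dx1 * matrix(bc_channel(cache$gc, d), C), d)
  dgc <- sum_spatial(array(dx1 * xm, d))        # (C,N)
  ds <- dgc * cache$gc * (1 - cache$gc)
  b_a2 <- linear_bwd(ds, cache$a2$cache, p$W2)
  b_m2 <- linear_bwd(ds, cache$m2$cache, p$W2)
  b_ar <- relu_bwd(b_a2$dx, cache$ar$cache)
  b_mr <- relu_bwd(b_m2$dx, cache$mr$cache)
  b_a1 <- linear_bwd(b_ar, cache$a1$cache, p$W1)
  b_m1 <- linear_bwd(b_mr, cache$m1$cache, p$W1)
  dx <- dx + gap_bwd(b_a1$dx, cache$ga$cache) + gmp_bwd(b_m1$dx, cache$gm$cache)
  list(dx = dx,
       grads = list(W1 = b_a1$dW + b_m1$dW, b1 = b_a1$db + b_m1$db,
                    W2 = b_a2$dW + b_m2$dW, b2 = b_a2$db + b_m2$db,
                    Ws = cb$dW, bs = cb$db))
}

## ---- ParNet SSE -----------------------------------------------------------

parnet_fwd <- function(layer, x, training = TRUE) {
  d <- dim(x)
  ga <- gap_fwd(x)
  l <- linear_fwd(ga$y, layer$par$W, layer$par$b)
  g <- sigmoid(l$y)                             # (C,N)
  y <- x * bc_channel(g, d)
  list(y = y, layer = layer,
       cache = list(d = d, ga = ga, l = l, g = g, x = x))
}

parnet_bwd <- function(layer, dy, cache) {
  d <- cache$d
  C <- d[1L]
  dyM <- matrix(dy, C)
  g <- cache$g
  dx <- array(dyM * matrix(bc_channel(g, d), C), d)
  dg <- sum_spatial(array(dyM * matrix(cache$x, C), d))
  ds <- dg * g * (1 - g)
  bl <- linear_bwd(ds, cache$l$cache, layer$par$W)
  dx <- dx + gap_bwd(bl$dx, cache$ga$cache)
  list(dx = dx, grads = list(W = bl$dW, b = bl$db))
}

## ---- user-facing single-map wrappers --------------------------------------

#' Apply an attention module to a single feature map
#'
#' @param att module from [new_attention()].
#' @param f `C x H x W` numeric array.
#' @return gated feature map of the same shape.
#' @export
apply_attention <- function(att, f) {
  stopifnot(inherits(att, "cowreid_attention"), length(dim(f)) == 3L)
  xb <- array(f, c(dim(f), 1L))
  y <- switch(att$kind,
    att_simam = simam_fwd(xb, att$cfg$lambda)$y,
    att_cbam = cbam_fwd(att, xb)$y,
    att_parnet = parnet_fwd(att, xb)$y,
    stop("unknown attention kind"))
  array(y, dim(f))
}

#' Parameter-free SimAM attention on a single feature map
#'
#' Reweights every position by a sigmoid of its inverse energy, computed from
#' the per-channel spatial mean and variance; adds zero learnable parameters.
#'
#' @param f `C x H x W` numeric array with at least 2 spatial positions.
#' @param lambda stability constant added to the variance.
#' @return gated feature map of the same shape.
#' @export
attention_simam <- function(f, lambda = 1e-4) {
  if (is.matrix(f)) f <- array(f, c(1L, dim(f)))
  array(simam_fwd(array(f, c(dim(f), 1L)), lambda)$y, dim(f))
}
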