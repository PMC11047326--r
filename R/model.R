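# The ResSTN embedding network: residual backbone -> attention at the end of
# each stage-3/4 residual block -> spatial transformer on the stage-4 feature
# map -> global average pooling -> embedding. A separate class-weight head
# provides closed-set scores for validation metrics.

new_conv_layer <- function(c_in, c_out, k = 3L, stride = 1L, pad = 1L) {
  structure(list(kind = "conv",
                 cfg = list(stride = stride, pad = pad),
                 par = list(W = conv2d_init(c_in, c_out, k))),
            class = "cowreid_layer")
}

new_bn_layer <- function(channels) {
  structure(list(kind = "bn",
                 cfg = list(momentum = 0.1),
                 par = list(gamma = rep(1, channels), beta = numeric(channels)),
                 buf = list(rmean = numeric(channels), rvar = rep(1, channels))),
            class = "cowreid_layer")
}

# Recursively set the running-statistics momentum of every BN layer (used by
# the precise-BN re-estimation pass after training).
set_bn_momentum <- function(layer, momentum) {
  if (identical(layer$kind, "bn")) layer$cfg$momentum <- momentum
  if (!is.null(layer$sub)) {
    layer$sub <- lapply(layer$sub, set_bn_momentum, momentum = momentum)
  }
  layer
}

new_relu_layer <- function() {
  structure(list(kind = "relu", par = list()), class = "cowreid_layer")
}

new_resblock <- function(c_in, c_out, stride = 1L, attention = "none",
                         lambda = 1e-4) {
  sub <- list(conv1 = new_conv_layer(c_in, c_out, stride = stride),
              bn1 = new_bn_layer(c_out),
              conv2 = new_conv_layer(c_out, c_out),
              bn2 = new_bn_layer(c_out))
  if (stride != 1L || c_in != c_out) {
    sub$down_conv <- new_conv_layer(c_in, c_out, k = 1L, stride = stride,
                                    pad = 0L)
    sub$down_bn <- new_bn_layer(c_out)
  }
  if (attention != "none") {
    sub$att <- new_attention(tolower(attention), c_out, lambda = lambda)
  }
  structure(list(kind = "resblock", cfg = list(), par = list(), sub = sub),
            class = "cowreid_layer")
}

## ---- generic dispatch -----------------------------------------------------

layer_fwd <- function(layer, x, training = TRUE) {
  switch(layer$kind,
    conv = {
      r <- conv2d_fwd(x, layer$par$W, NULL, layer$cfg$stride, layer$cfg$pad)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    bn = {
      r <- bn_fwd(x, layer$par$gamma, layer$par$beta,
                  layer$buf$rmean, layer$buf$rvar, training,
                  momentum = layer$cfg$momentum %||% 0.1)
      layer$buf$rmean <- r$rmean
      layer$buf$rvar <- r$rvar
      list(y = r$y, cache = r$cache, layer = layer)
    },
    relu = {
      r <- relu_fwd(x)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    att_simam = {
      r <- simam_fwd(x, layer$cfg$lambda)
      list(y = r$y, cache = r$cache, layer = layer)
    },
    att_cbam = cbam_fwd(layer, x, training),
    att_parnet = parnet_fwd(layer, x, training),
    stn = stn_layer_fwd(layer, x, training),
    resblock = resblock_fwd(layer, x, training),
    stop("unknown layer kind: ", layer$kind))
}

layer_bwd <- function(layer, dy, cache) {
  switch(layer$kind,
    conv = {
      r <- conv2d_bwd(dy, cache, layer$par$W)
      list(dx = r$dx, grads = list(par = list(W = r$dW)))
    },
    bn = {
      r <- bn_bwd(dy, cache, layer$par$gamma)
      list(dx = r$dx, grads = list(par = list(gamma = r$dgamma,
                                              beta = r$dbeta)))
    },
    relu = list(dx = relu_bwd(dy, cache), grads = list(par = list())),
    att_simam = list(dx = simam_bwd(dy, cache), grads = list(par = list())),
    att_cbam = {
      r <- cbam_bwd(layer, dy, cache)
      list(dx = r$dx, grads = list(par = r$grads))
    },
    att_parnet = {
      r <- parnet_bwd(layer, dy, cache)
      list(dx = r$dx, grads = list(par = r$grads))
    },
    stn = {
      r <- stn_layer_bwd(layer, dy, cache)
      list(dx = r$dx, grads = list(par = r$grads))
    },
    resblock = resblock_bwd(layer, dy, cache),
    stop("unknown layer kind: ", layer$kind))
}

resblock_fwd <- function(layer, x, training = TRUE) {
  s <- layer$sub
  c1 <- layer_fwd(s$conv1, x, training)
  b1 <- layer_fwd(s$bn1, c1$y, training); s$bn1 <- b1$layer
  r1 <- relu_fwd(b1$y)
  c2 <- layer_fwd(s$conv2, r1$y, training)
  b2 <- layer_fwd(s$bn2, c2$y, training); s$bn2 <- b2$layer
  if (!is.null(s$down_conv)) {
    dc <- layer_fwd(s$down_conv, x, training)
    db <- layer_fwd(s$down_bn, dc$y, training); s$down_bn <- db$layer
    shortcut <- db$y
    short_cache <- list(dc = dc$cache, db = db$cache)
  } else {
    shortcut <- x
    short_cache <- NULL
  }
  r2 <- relu_fwd(b2$y + shortcut)
  y <- r2$y
  att_cache <- NULL
  if (!is.null(s$att)) {
    af <- layer_fwd(s$att, y, training)
    y <- af$y
    att_cache <- af$cache
    s$att <- af$layer
  }
  layer$sub <- s
  list(y = y, layer = layer,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, short = short_cache,
                    r2 = r2$cache, att = att_cache))
}

resblock_bwd <- function(layer, dy, cache) {
  s <- layer$sub
  grads <- list(par = list(), sub = list())
  if (!is.null(s$att)) {
    r <- layer_bwd(s$att, dy, cache$att)
    grads$sub$att <- r$grads
    dy <- r$dx
  }
  dpre <- relu_bwd(dy, cache$r2)
  # shortcut branch
  if (!is.null(s$down_conv)) {
    rdb <- layer_bwd(s$down_bn, dpre, cache$short$db)
    rdc <- layer_bwd(s$down_conv, rdb$dx, cache$short$dc)
    grads$sub$down_bn <- rdb$grads
    grads$sub$down_conv <- rdc$grads
    dx_short <- rdc$dx
  } else {
    dx_short <- dpre
  }
  # main branch
  rb2 <- layer_bwd(s$bn2, dpre, cache$b2)
  rc2 <- layer_bwd(s$conv2, rb2$dx, cache$c2)
  dr1 <- relu_bwd(rc2$dx, cache$r1)
  rb1 <- layer_bwd(s$bn1, dr1, cache$b1)
  rc1 <- layer_bwd(s$conv1, rb1$dx, cache$c1)
  grads$sub$bn2 <- rb2$grads
  grads$sub$conv2 <- rc2$grads
  grads$sub$bn1 <- rb1$grads
  grads$sub$conv1 <- rc1$grads
  list(dx = rc1$dx + dx_short, grads = grads)
}

## ---- model ----------------------------------------------------------------

#' Backbone and embedding configuration
#'
#' @param depth_preset `"tiny"` (2 basic blocks per stage, narrow channels,
#'   32x32 input; trains in seconds per epoch on one CPU), `"resnet18"`, or
#'   `"resnet101"` (3-4-23-3 blocks; construction-scale fidelity, not meant
#'   for CPU training).
#' @param stage_channels integer vector of 4 channel counts; defaults depend
#'   on the preset.
#' @param attention `"none"`, `"cbam"`, `"simam"` or `"parnet"`; the module is
#'   inserted at the end of each residual block of the stages in
#'   `attention_stages`.
#' @param attention_stages integer subset of 1:4 (default `c(3, 4)`).
#' @param input_size spatial size (images are resized to
#'   `input_size x input_size` after orientation normalization).
#' @param in_channels image channels (1 for grayscale).
#' @param use_stn apply the spatial transformer to the stage-4 feature map.
#' @param loc_hidden hidden width of the STN localization network.
#' @param simam_lambda SimAM stability constant.
#' @return a `cowreid_config` list; `embedding_dim` equals
#'   `stage_channels[4]` (the embedding is the global average pool of the
#'   transformed stage-4 map).
#' @export
backbone_config <- function(depth_preset = c("tiny", "resnet18", "resnet101"),
                            stage_channels = NULL,
                            attention = c("none", "cbam", "simam", "parnet"),
                            attention_stages = c(3L, 4L),
                            input_size = NULL, in_channels = 1L,
                            use_stn = TRUE, loc_hidden = 64L,
                            simam_lambda = 1e-4) {
  depth_preset <- match.arg(depth_preset)
  attention <- match.arg(attention)
  stopifnot(all(attention_stages %in% 1:4))
  blocks <- switch(depth_preset,
                   tiny = c(2L, 2L, 2L, 2L),
                   resnet18 = c(2L, 2L, 2L, 2L),
                   resnet101 = c(3L, 4L, 23L, 3L))
  if (is.null(stage_channels)) {
    stage_channels <- switch(depth_preset,
                             tiny = c(8L, 16L, 24L, 32L),
                             resnet18 = c(64L, 128L, 256L, 512L),
                             resnet101 = c(64L, 128L, 256L, 512L))
  }
  stopifnot(length(stage_channels) == 4L)
  if (is.null(input_size)) {
    input_size <- if (depth_preset == "tiny") 32L else 224L
  }
  structure(list(depth_preset = depth_preset, blocks = blocks,
                 stage_channels = stage_channels, attention = attention,
                 attention_stages = as.integer(attention_stages),
                 embedding_dim = stage_channels[4L],
                 input_size = as.integer(input_size),
                 in_channels = as.integer(in_channels),
                 use_stn = isTRUE(use_stn), loc_hidden = as.integer(loc_hidden),
                 simam_lambda = simam_lambda),
            class = "cowreid_config")
}

#' Construct an untrained embedding network
#'
#' @param config from [backbone_config()].
#' @param n_classes number of training identities (rows of the classification
#'   head); 0 for a headless embedding network.
#' @param seed integer seed for weight initialization.
#' @return object of class `cowreid_model`.
#' @export
new_model <- function(config, n_classes = 0L, seed = 1L) {
  stopifnot(inherits(config, "cowreid_config"))
  set.seed(seed)
  ch <- config$stage_channels
  layers <- list(stem_conv = new_conv_layer(config$in_channels, ch[1L]),
                 stem_bn = new_bn_layer(ch[1L]),
                 stem_relu = new_relu_layer())
  c_in <- ch[1L]
  for (stage in 1:4) {
    att <- if (stage %in% config$attention_stages) config$attention else "none"
    for (b in seq_len(config$blocks[stage])) {
      stride <- if (stage > 1L && b == 1L) 2L else 1L
      nm <- sprintf("stage%d_block%d", stage, b)
      layers[[nm]] <- new_resblock(c_in, ch[stage], stride, att,
                                   config$simam_lambda)
      c_in <- ch[stage]
    }
  }
  if (config$use_stn) {
    layers$stn <- new_stn(ch[4L], config$loc_hidden)
  }
  head <- if (n_classes > 0L) {
    matrix(stats::rnorm(n_classes * config$embedding_dim,
                        sd = 1 / sqrt(config$embedding_dim)),
           n_classes, config$embedding_dim)
  }
  structure(list(config = config, layers = layers, head = head,
                 n_classes = as.integer(n_classes)),
            class = "cowreid_model")
}

# Full forward pass. x is (C,H,W,N). Returns embeddings (dim,N) plus per-layer
# caches for backward; the model is returned because BN updates running stats.
model_forward <- function(model, x, training = TRUE) {
  caches <- vector("list", length(model$layers))
  names(caches) <- names(model$layers)
  for (nm in names(model$layers)) {
    r <- layer_fwd(model$layers[[nm]], x, training)
    x <- r$y
    caches[[nm]] <- r$cache
    model$layers[[nm]] <- r$layer
  }
  gp <- gap_fwd(x)
  list(emb = gp$y, caches = caches, gap_cache = gp$cache, model = model)
}

# Backward from embedding gradient (dim,N); returns grads mirroring layers.
model_backward <- function(model, fw, demb) {
  dy <- gap_bwd(demb, fw$gap_cache)
  grads <- vector("list", length(model$layers))
  names(grads) <- names(model$layers)
  for (nm in rev(names(model$layers))) {
    r <- layer_bwd(model$layers[[nm]], dy, fw$caches[[nm]])
    grads[[nm]] <- r$grads
    dy <- r$dx
  }
  grads
}

#' Compute embeddings for a batch of images
#'
#' Runs the network in evaluation mode (batch-norm running statistics, no
#' augmentation); deterministic for fixed weights.
#'
#' @param model a `cowreid_model`.
#' @param images list of numeric matrices (grayscale) or `C x H x W` arrays,
#'   already sized to `model$config$input_size`; alternatively a single
#'   `(C,H,W,N)` array.
#' @return `N x embedding_dim` matrix, one row per image.
#' @export
embed <- function(model, images) {
  stopifnot(inherits(model, "cowreid_model"))
  x <- stack_images(images, model$config)
  fw <- model_forward(model, x, training = FALSE)
  t(fw$emb)
}

stack_images <- function(images, config) {
  s <- config$input_size
  if (is.array(images) && length(dim(images)) == 4L) {
    x <- images
  } else {
    if (!is.list(images)) images <- list(images)
    n <- length(images)
    x <- array(0, c(config$in_channels, s, s, n))
    for (i in seq_len(n)) {
      im <- images[[i]]
      if (inherits(im, "labeled_image")) im <- im$pixels
      if (is.matrix(im)) im <- array(im, c(1L, dim(im)))
      if (!all(dim(im) == c(config$in_channels, s, s))) {
        stop("images must be preprocessed to the configured input size (",
             s, "x", s, ")")
      }
      x[, , , i] <- im
    }
  }
  if (!all(dim(x)[2:3] == s)) {
    stop("images must be preprocessed to the configured input size (",
         s, "x", s, ")")
  }
  x
}

#' Closed-set identity scores for embeddings
#'
#' Angular losses score by cosine against L2-normalized head rows; otherwise
#' plain inner products are used.
#'
#' @param emb numeric vector (one embedding) or `N x dim` matrix.
#' @param head `C x dim` class-weight matrix (one row per known identity).
#' @param mode `"cosine"` or `"dot"`.
#' @return `N x C` score matrix.
#' @export
classify <- function(emb, head, mode = c("cosine", "dot")) {
  mode <- match.arg(mode)
  if (is.null(dim(emb))) emb <- matrix(emb, 1L)
  stopifnot(ncol(emb) == ncol(head))
  if (mode == "cosine") {
    en <- emb / pmax(sqrt(rowSums(emb^2)), 1e-12)
    hn <- head / pmax(sqrt(rowSums(head^2)), 1e-12)
    en %*% t(hn)
  } else {
    emb %*% t(head)
  }
}

#' Save / load a model checkpoint
#'
#' Checkpoints are single-file RDS snapshots of weights, configuration and
#' (optionally) training state.
#'
#' @param model a `cowreid_model`.
#' @param path file path.
#' @param extra optional list stored alongside the model (e.g. training log).
#' @return `save_checkpoint` returns `path` invisibly; `load_checkpoint`
#'   returns `list(model, extra)`.
#' @export
save_checkpoint <- function(model, path, extra = NULL) {
  saveRDS(list(model = model, extra = extra, version = "1"), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  stopifnot(inherits(obj$model, "cowreid_model"))
  obj[c("model", "extra")]
}

## ---- SGD ------------------------------------------------------------------

make_momentum_state <- function(layer) {
  st <- list(par = lapply(layer$par, function(p) p * 0))
  if (!is.null(layer$sub)) st$sub <- lapply(layer$sub, make_momentum_state)
  st
}

sgd_update_layer <- function(layer, grads, state, lr, momentum, wd) {
  for (nm in names(layer$par)) {
    g <- grads$par[[nm]] + wd * layer$par[[nm]]
    v <- momentum * state$par[[nm]] + g
    state$par[[nm]] <- v
    layer$par[[nm]] <- layer$par[[nm]] - lr * v
  }
  if (!is.null(layer$sub)) {
    for (nm in names(layer$sub)) {
      r <- sgd_update_layer(layer$sub[[nm]], grads$sub[[nm]],
                            state$sub[[nm]], lr, momentum, wd)
      layer$sub[[nm]] <- r$layer
      state$sub[[nm]] <- r$state
    }
  }
  list(layer = layer, state = state)
}
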