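# SGD training of the embedding network with the four metric-learning losses,
# per-epoch validation top-1/top-5, and checkpointing of the best model.

#' Training configuration
#'
#' Defaults are desk-scale (single CPU): batch size 32 and 10 epochs with the
#' tiny backbone. `paper_scale = TRUE` switches to the full-study settings
#' (batch 96, 50 epochs) while keeping identical optimizer semantics: SGD
#' with momentum 0.9, weight decay 1e-4, initial learning rate 0.02, a linear
#' warm-up over the first 5 epochs and a linear decay thereafter, updated per
#' epoch.
#'
#' @param learning_rate initial learning rate.
#' @param momentum SGD momentum.
#' @param weight_decay L2 weight decay.
#' @param batch_size images per step.
#' @param max_epochs total epochs.
#' @param warmup_epochs epochs of linear warm-up.
#' @param warmup_start_factor learning-rate factor at epoch 1.
#' @param end_factor learning-rate factor at `max_epochs`.
#' @param seed training seed (shuffling, augmentation, initialization).
#' @param paper_scale use the full-study batch size and epoch count.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.02, momentum = 0.9,
                         weight_decay = 1e-4, batch_size = 32L,
                         max_epochs = 10L, warmup_epochs = 5L,
                         warmup_start_factor = 0.1, end_factor = 0.01,
                         seed = 1L, paper_scale = FALSE) {
  if (paper_scale) {
    batch_size <- 96L
    max_epochs <- 50L
  }
  stopifnot(learning_rate > 0, max_epochs >= 1, warmup_epochs < max_epochs)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 weight_decay = weight_decay, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 warmup_epochs = as.integer(warmup_epochs),
                 warmup_start_factor = warmup_start_factor,
                 end_factor = end_factor, seed = as.integer(seed)),
            class = "train_config")
}

#' Learning rate at a given epoch
#'
#' Linear warm-up from `warmup_start_factor` to 1 across epochs
#' `1..warmup_epochs`, then linear decay from 1 to `end_factor` across the
#' remaining epochs; the factor multiplies `learning_rate`.
#'
#' @param epoch epoch index (1-based).
#' @param config a [train_config()].
#' @return scalar learning rate.
#' @export
lr_schedule <- function(epoch, config) {
  w <- config$warmup_epochs
  f <- if (epoch <= w) {
    config$warmup_start_factor +
      (1 - config$warmup_start_factor) * (epoch - 1) / max(1L, w - 1L)
  } else {
    1 + (config$end_factor - 1) * (epoch - w) / (config$max_epochs - w)
  }
  config$learning_rate * f
}

#' Train an embedding network on a synthetic dataset split
#'
#' Images are orientation-normalized, augmented (training images only; see
#' `augment_cfg`), resized and batched; the configured loss drives SGD with
#' the warm-up/decay schedule of [lr_schedule()]. Contrastive and center
#' losses are trained jointly with a plain softmax cross-entropy term (the
#' quadratic losses alone cannot train a classifier without collapse); the
#' margin losses train the class head directly. Validation top-1/top-5 is
#' computed every epoch and the best-by-top-1 weights are returned.
#'
#' @param model from [new_model()]; its head must have one row per training
#'   identity.
#' @param split a `dataset_split` from [generate_dataset()].
#' @param config a [train_config()].
#' @param loss `"arcface"`, `"cosface"`, `"contrastive"` or `"center"`.
#' @param loss_cfg list of loss hyperparameters: `s`, `m` (margin losses),
#'   `margin` (contrastive), `center_lambda`, `update_rate` (center).
#' @param augment_cfg an [augment_config()], or NULL to disable augmentation.
#' @param precise_bn after the last epoch, re-estimate the batch-norm running
#'   statistics over un-augmented training images (cumulative averages over
#'   `precise_bn_batches` batches). With few SGD steps the exponentially
#'   smoothed statistics lag the final weights; re-estimation aligns
#'   evaluation-mode activations with the weights actually saved.
#' @param precise_bn_batches number of re-estimation batches.
#' @param verbose print one line per epoch.
#' @return list with `model` (best by validation top-1), `final_model` (the
#'   weights after the last epoch), `log` (data frame: epoch, lr, loss,
#'   val_top1, val_top5).
#' @export
train_model <- function(model, split, config = train_config(),
                        loss = c("arcface", "cosface", "contrastive", "center"),
                        loss_cfg = list(), augment_cfg = augment_config(),
                        precise_bn = TRUE, precise_bn_batches = 8L,
                        verbose = FALSE) {
  loss <- match.arg(loss)
  lc <- utils::modifyList(list(s = 30, m = if (loss == "cosface") 0.35 else 0.5,
                               margin = 1, center_lambda = 0.01,
                               update_rate = 0.5), loss_cfg)
  train_ids <- sort(unique(vapply(split$train, function(im) im$identity,
                                  integer(1))))
  stopifnot(nrow(model$head) == length(train_ids))
  id_to_class <- stats::setNames(seq_along(train_ids), train_ids)
  y_train <- id_to_class[as.character(vapply(split$train,
                                             function(im) im$identity,
                                             integer(1)))]
  y_val <- id_to_class[as.character(vapply(split$val,
                                           function(im) im$identity,
                                           integer(1)))]
  size <- model$config$input_size
  set.seed(config$seed)
  mstate <- lapply(model$layers, make_momentum_state)
  hstate <- model$head * 0
  centers <- if (loss == "center") {
    matrix(0, nrow(model$head), model$config$embedding_dim)
  }
  angular <- loss %in% c("arcface", "cosface")
  # validation tensors are fixed across epochs (no augmentation)
  xval <- if (length(split$val)) {
    stack_images(lapply(split$val, preprocess_image, input_size = size),
                 model$config)
  }
  log <- NULL
  best <- list(top1 = -1, model = model)
  n <- length(split$train)
  for (epoch in seq_len(config$max_epochs)) {
    lr <- lr_schedule(epoch, config)
    ord <- sample.int(n)
    ep_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      if (length(idx) < 2L) next
      aug_seeds <- sample.int(.Machine$integer.max - 1L, length(idx))
      imgs <- lapply(seq_along(idx), function(i) {
        preprocess_image(split$train[[idx[i]]], size, augment_cfg,
                         aug_seeds[i])
      })
      x <- stack_images(imgs, model$config)
      yb <- y_train[idx]
      fw <- model_forward(model, x, training = TRUE)
      model <- fw$model
      emb <- t(fw$emb)
      lres <- switch(loss,
        arcface = arcface_loss(emb, yb, model$head, lc$s, lc$m),
        cosface = cosface_loss(emb, yb, model$head, lc$s, lc$m),
        contrastive = {
          ce <- softmax_ce_loss(emb, yb, model$head)
          pr <- build_batch_pairs(yb)
          if (!is.null(pr)) {
            co <- contrastive_loss(emb[pr$i, , drop = FALSE],
                                   emb[pr$j, , drop = FALSE], pr$y, lc$margin)
            demb <- ce$d_embeddings
            for (t in seq_along(pr$i)) {
              demb[pr$i[t], ] <- demb[pr$i[t], ] + co$d_a[t, ]
              demb[pr$j[t], ] <- demb[pr$j[t], ] + co$d_b[t, ]
            }
            list(loss = ce$loss + co$loss, d_embeddings = demb,
                 d_weights = ce$d_weights)
          } else ce
        },
        center = {
          ce <- softmax_ce_loss(emb, yb, model$head)
          cl <- center_loss(emb, yb, centers)
          list(loss = ce$loss + lc$center_lambda * cl$loss,
               d_embeddings = ce$d_embeddings +
                 lc$center_lambda * cl$d_embeddings,
               d_weights = ce$d_weights)
        })
      if (loss == "center") {
        centers <- center_update(centers, emb, yb, lc$update_rate)
      }
      if (!is.finite(lres$loss)) stop("non-finite loss at epoch ", epoch)
      grads <- model_backward(model, fw, t(lres$d_embeddings))
      for (nm in names(model$layers)) {
        r <- sgd_update_layer(model$layers[[nm]], grads[[nm]], mstate[[nm]],
                              lr, config$momentum, config$weight_decay)
        model$layers[[nm]] <- r$layer
        mstate[[nm]] <- r$state
      }
      gh <- lres$d_weights + config$weight_decay * model$head
      hstate <- config$momentum * hstate + gh
      model$head <- model$head - lr * hstate
      ep_loss <- ep_loss + lres$loss
      n_batches <- n_batches + 1L
    }
    top1 <- NA_real_; top5 <- NA_real_
    if (!is.null(xval)) {
      scores <- classify(t(model_forward(model, xval, training = FALSE)$emb),
                         model$head, if (angular) "cosine" else "dot")
      top1 <- topk_accuracy(scores, y_val, 1L)
      top5 <- topk_accuracy(scores, y_val, 5L)
      if (top1 >= best$top1) best <- list(top1 = top1, model = model)
    } else {
      best <- list(top1 = NA_real_, model = model)
    }
    log <- rbind(log, data.frame(epoch = epoch, lr = lr,
                                 loss = ep_loss / max(1L, n_batches),
                                 val_top1 = top1, val_top5 = top5))
    if (verbose) {
      message(sprintf("epoch %2d  lr %.4f  loss %.4f  val top-1 %.3f top-5 %.3f",
                      epoch, lr, log$loss[epoch], top1, top5))
    }
  }
  if (precise_bn) {
    best$model <- refresh_bn_stats(best$model, split$train,
                                   n_batches = precise_bn_batches,
                                   batch_size = config$batch_size)
    model <- refresh_bn_stats(model, split$train,
                              n_batches = precise_bn_batches,
                              batch_size = config$batch_size)
  }
  list(model = best$model, final_model = model, log = log)
}

# Precise-BN pass: cumulative running statistics over clean training renders.
# Batches must mix identities (images arrive grouped by identity, and
# homogeneous batches bias the variance estimates low), so the order is
# shuffled; deterministic given the caller's RNG state.
refresh_bn_stats <- function(model, images, n_batches = 8L, batch_size = 32L) {
  size <- model$config$input_size
  idx <- sample(rep_len(seq_along(images), n_batches * batch_size))
  for (b in seq_len(n_batches)) {
    # momentum 1/b turns the running stats into a cumulative average
    model$layers <- lapply(model$layers, set_bn_momentum, momentum = 1 / b)
    take <- idx[((b - 1L) * batch_size + 1L):(b * batch_size)]
    imgs <- lapply(images[take], preprocess_image, input_size = size)
    x <- stack_images(imgs, model$config)
    model <- model_forward(model, x, training = TRUE)$model
  }
  model$layers <- lapply(model$layers, set_bn_momentum, momentum = 0.1)
  model
}

#' Open-set evaluation of a trained model
#'
#' Embeds the held-out test images of identities never seen in training,
#' builds balanced verification pairs, and calibrates the decision threshold
#' by ten-fold cross-validation.
#'
#' @param model trained `cowreid_model`.
#' @param split a `dataset_split` (its `test` images are used).
#' @param n_pairs positive pair count (an equal number of negatives is drawn).
#' @param metric distance metric name.
#' @param seed pair-sampling and fold seed.
#' @param augment_eval also augment the evaluation images (off by default:
#'   randomized test-time augmentation makes accuracy seed-dependent).
#' @param augment_cfg used only when `augment_eval = TRUE`.
#' @return a `calibration_report` (see [calibrate()]).
#' @export
evaluate_openset <- function(model, split, n_pairs = 100L, metric = "cosine",
                             seed = 1L, augment_eval = FALSE,
                             augment_cfg = augment_config()) {
  size <- model$config$input_size
  set.seed(seed)
  aug_seeds <- sample.int(.Machine$integer.max - 1L, length(split$test))
  imgs <- lapply(seq_along(split$test), function(i) {
    preprocess_image(split$test[[i]], size,
                     if (augment_eval) augment_cfg else NULL, aug_seeds[i])
  })
  emb <- embed(model, imgs)
  pairs <- make_pairs(split$test, n_pairs, n_pairs, seed = seed)
  calibrate(emb, pairs, metric = metric, seed = seed)
}
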