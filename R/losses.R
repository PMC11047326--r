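# Metric-learning losses.
#
# ArcFace adds an additive angular margin m (radians) to the target angle
# before the scaled softmax; CosFace subtracts a cosine margin from the target
# cosine; the contrastive loss pulls same-class pairs together and pushes
# different-class pairs beyond a distance margin (label convention: 0 = same
# class, 1 = different); the center loss penalizes squared distance to the
# running class centers. All return analytic gradients, verified against
# central finite differences in the tests.

normalize_rows <- function(m, eps = 1e-12) {
  nr <- sqrt(rowSums(m^2))
  if (any(nr < eps)) stop("zero-norm vector: angles are undefined")
  list(y = m / nr, norms = nr)
}

# Shared margin-softmax machinery: `target_fn` maps the target cosines to
# margin-penalized target logit values and their derivative wrt the cosine.
margin_softmax <- function(embeddings, labels, weights, s, target_fn,
                           eps = 1e-14) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, 1L)
  N <- nrow(embeddings)
  C <- nrow(weights)
  labels <- as.integer(labels)
  stopifnot(length(labels) == N, all(labels >= 1L), all(labels <= C),
            ncol(embeddings) == ncol(weights), s > 0)
  en <- normalize_rows(embeddings)
  wn <- normalize_rows(weights)
  cosm <- en$y %*% t(wn$y)
  cosm <- pmin(pmax(cosm, -1 + eps), 1 - eps)
  ti <- cbind(seq_len(N), labels)
  tf <- target_fn(cosm[ti])
  logits <- s * cosm
  logits[ti] <- s * tf$value
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  p <- ex / rowSums(ex)
  loss <- -mean(log(p[ti]))
  # backward
  dlogits <- p / N
  dlogits[ti] <- dlogits[ti] - 1 / N
  dcos <- s * dlogits
  dcos[ti] <- dcos[ti] * tf$deriv
  # through the normalized cosine similarity
  dEn <- dcos %*% wn$y
  dWn <- crossprod(dcos, en$y)
  d_emb <- (dEn - en$y * rowSums(dEn * en$y)) / en$norms
  d_w <- (dWn - wn$y * rowSums(dWn * wn$y)) / wn$norms
  list(loss = loss, d_embeddings = d_emb, d_weights = d_w)
}

#' ArcFace (additive angular margin) loss
#'
#' `L = -(1/N) sum log[ exp(s cos(theta_yi + m)) /
#'   (exp(s cos(theta_yi + m)) + sum_{j != yi} exp(s cos theta_j)) ]`, with
#' `theta` the angle between the L2-normalized embedding and the normalized
#' class-weight row. Cosines are clamped away from +-1 before the angle
#' arithmetic for numerical stability.
#'
#' @param embeddings `N x dim` matrix (rows are embedding vectors).
#' @param labels integer class indices in `1..C`.
#' @param weights `C x dim` class-weight matrix.
#' @param s scale parameter (> 0).
#' @param m margin; radians for ArcFace in `[0, pi)`, cosine units in
#'   `[0, 1)` for CosFace.
#' @return list with `loss` (scalar), `d_embeddings` and `d_weights`
#'   (gradients of the mean loss).
#' @export
arcface_loss <- function(embeddings, labels, weights, s = 30, m = 0.5) {
  stopifnot(m >= 0, m < pi)
  cm <- cos(m); sm <- sin(m)
  margin_softmax(embeddings, labels, weights, s, function(cy) {
    sq <- sqrt(pmax(1 - cy^2, 1e-12))
    list(value = cy * cm - sq * sm, deriv = cm + cy / sq * sm)
  })
}

#' CosFace (additive cosine margin) loss
#'
#' `L = -(1/N) sum log[ exp(s (cos theta_yi - m)) /
#'   (exp(s (cos theta_yi - m)) + sum_{j != yi} exp(s cos theta_j)) ]`.
#' Equals [arcface_loss()] exactly at `m = 0`.
#'
#' @inheritParams arcface_loss
#' @return as [arcface_loss()].
#' @export
cosface_loss <- function(embeddings, labels, weights, s = 30, m = 0.35) {
  stopifnot(m >= 0, m < 1)
  margin_softmax(embeddings, labels, weights, s, function(cy) {
    list(value = cy - m, deriv = rep(1, length(cy)))
  })
}

# Plain softmax cross-entropy on inner-product logits (used as the
# classification term when training with the contrastive or center loss).
softmax_ce_loss <- function(embeddings, labels, weights) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, 1L)
  N <- nrow(embeddings)
  labels <- as.integer(labels)
  logits <- embeddings %*% t(weights)
  mx <- apply(logits, 1L, max)
  ex <- exp(logits - mx)
  p <- ex / rowSums(ex)
  ti <- cbind(seq_len(N), labels)
  loss <- -mean(log(pmax(p[ti], 1e-300)))
  dlogits <- p / N
  dlogits[ti] <- dlogits[ti] - 1 / N
  list(loss = loss, d_embeddings = dlogits %*% weights,
       d_weights = crossprod(dlogits, embeddings))
}

#' Contrastive loss on embedding pairs
#'
#' `L = (1/2N) sum [(1 - y) d^2 + y max(0, m - d)^2]` with
#' `d = ||f_a - f_b||_2` and the label convention `y = 0` for a same-class
#' pair and `y = 1` for a different-class pair.
#'
#' @param emb_a,emb_b `N x dim` matrices of paired embeddings.
#' @param labels integer vector, 0 = same class, 1 = different class.
#' @param margin minimum inter-class distance boundary (> 0).
#' @return list with `loss`, `d_a`, `d_b`.
#' @export
contrastive_loss <- function(emb_a, emb_b, labels, margin = 1) {
  if (is.null(dim(emb_a))) emb_a <- matrix(emb_a, 1L)
  if (is.null(dim(emb_b))) emb_b <- matrix(emb_b, 1L)
  stopifnot(margin > 0, all(labels %in% c(0, 1)),
            all(dim(emb_a) == dim(emb_b)), nrow(emb_a) == length(labels))
  N <- nrow(emb_a)
  diff <- emb_a - emb_b
  d <- sqrt(rowSums(diff^2))
  hinge <- pmax(0, margin - d)
  loss <- sum((1 - labels) * d^2 + labels * hinge^2) / (2 * N)
  # gradient; the hinge term at d = 0 has a removable 0/0, set to 0
  unit <- diff / ifelse(d > 1e-12, d, 1)
  d_a <- ((1 - labels) * diff - labels * hinge * unit) / N
  list(loss = loss, d_a = d_a, d_b = -d_a)
}

#' Center loss and center update
#'
#' `L = (1/2) sum_i ||f_i - c_{y_i}||^2` against per-class feature centers.
#' `center_update()` moves each center that appears in the batch toward the
#' batch mean of its class members by an `update_rate` fraction.
#'
#' @param embeddings `N x dim` matrix.
#' @param labels integer class indices in `1..C`.
#' @param centers `C x dim` matrix of class centers.
#' @return `center_loss`: list with `loss` and `d_embeddings`;
#'   `center_update`: the updated `C x dim` center matrix.
#' @export
center_loss <- function(embeddings, labels, centers) {
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, 1L)
  labels <- as.integer(labels)
  if (any(labels < 1L) || any(labels > nrow(centers))) {
    stop("label without a center row")
  }
  diff <- embeddings - centers[labels, , drop = FALSE]
  list(loss = 0.5 * sum(diff^2), d_embeddings = diff)
}

#' @rdname center_loss
#' @param update_rate fraction in (0, 1] of the distance to the batch mean
#'   that each present center moves.
#' @export
center_update <- function(centers, embeddings, labels, update_rate = 0.5) {
  stopifnot(update_rate > 0, update_rate <= 1)
  if (is.null(dim(embeddings))) embeddings <- matrix(embeddings, 1L)
  labels <- as.integer(labels)
  for (cl in unique(labels)) {
    mu <- colMeans(embeddings[labels == cl, , drop = FALSE])
    centers[cl, ] <- centers[cl, ] + update_rate * (mu - centers[cl, ])
  }
  centers
}

# In-batch pair construction for contrastive training: all same-class pairs
# plus an equal number of sampled different-class pairs.
build_batch_pairs <- function(labels) {
  n <- length(labels)
  cmb <- utils::combn(n, 2L)
  same <- labels[cmb[1L, ]] == labels[cmb[2L, ]]
  pos <- which(same)
  neg <- which(!same)
  if (length(pos) == 0L || length(neg) == 0L) return(NULL)
  neg <- sample(neg, min(length(neg), length(pos)))
  keep <- c(pos, neg)
  list(i = cmb[1L, keep], j = cmb[2L, keep],
       y = as.integer(!same[keep]))
}
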