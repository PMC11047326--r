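# Open-set pair verification: distance metrics with their threshold search
# grids, ten-fold cross-validated calibration, accuracy-weighted optimal
# threshold aggregation, and closed-set top-k accuracy.

#' Distance metric specification
#'
#' Threshold search ranges and exhaustive-search step sizes per metric:
#' euclidean `[0, 15]` step 0.01, cosine `[0, 1]` step 0.0001, mahalanobis
#' `[0, 5]` step 0.01, manhattan `[0, 100]` step 0.1. Cosine distance is
#' `1 - cosine similarity` (hence the `[0, 1]` range for non-negatively
#' correlated embeddings).
#'
#' @param name one of `"euclidean"`, `"cosine"`, `"mahalanobis"`,
#'   `"manhattan"`.
#' @param covariance positive-definite covariance matrix (mahalanobis only).
#' @return a `metric_spec` with fields `name`, `range`, `step`, `covariance`.
#' @export
metric_spec <- function(name = c("euclidean", "cosine", "mahalanobis",
                                 "manhattan"),
                        covariance = NULL) {
  name <- match.arg(name)
  range <- switch(name, euclidean = c(0, 15), cosine = c(0, 1),
                  mahalanobis = c(0, 5), manhattan = c(0, 100))
  step <- switch(name, euclidean = 0.01, cosine = 0.0001,
                 mahalanobis = 0.01, manhattan = 0.1)
  if (!is.null(covariance)) {
    ev <- eigen(covariance, symmetric = TRUE, only.values = TRUE)$values
    if (any(ev <= 0)) stop("mahalanobis covariance must be positive-definite")
  }
  structure(list(name = name, range = range, step = step,
                 covariance = covariance),
            class = "metric_spec")
}

#' Distance between two embedding vectors
#'
#' Euclidean `||f1 - f2||_2`; cosine `1 - f1.f2 / (||f1|| ||f2||)`;
#' mahalanobis `sqrt((f1 - f2)' Sigma^-1 (f1 - f2))`; manhattan
#' `||f1 - f2||_1`. All are symmetric and zero iff the inputs coincide
#' (cosine: iff they are positively colinear).
#'
#' @param f1,f2 equal-length finite numeric vectors.
#' @param spec a [metric_spec()]; mahalanobis requires its `covariance`.
#' @return scalar distance >= 0.
#' @export
distance <- function(f1, f2, spec) {
  stopifnot(inherits(spec, "metric_spec"), length(f1) == length(f2),
            all(is.finite(f1)), all(is.finite(f2)))
  d <- f1 - f2
  switch(spec$name,
    euclidean = sqrt(sum(d^2)),
    manhattan = sum(abs(d)),
    cosine = {
      n1 <- sqrt(sum(f1^2)); n2 <- sqrt(sum(f2^2))
      if (n1 == 0 || n2 == 0) stop("cosine distance undefined for zero-norm vectors")
      1 - sum(f1 * f2) / (n1 * n2)
    },
    mahalanobis = {
      if (is.null(spec$covariance)) stop("mahalanobis requires a covariance matrix")
      sqrt(drop(crossprod(d, solve(spec$covariance, d))))
    })
}

# Vectorized pair distances: embeddings N x dim, pairs data frame (a, b).
pair_distances <- function(embeddings, pairs, spec) {
  A <- embeddings[pairs$a, , drop = FALSE]
  B <- embeddings[pairs$b, , drop = FALSE]
  D <- A - B
  switch(spec$name,
    euclidean = sqrt(rowSums(D^2)),
    manhattan = rowSums(abs(D)),
    cosine = {
      na <- sqrt(rowSums(A^2)); nb <- sqrt(rowSums(B^2))
      if (any(na == 0 | nb == 0)) stop("cosine distance undefined for zero-norm vectors")
      1 - rowSums(A * B) / (na * nb)
    },
    mahalanobis = {
      if (is.null(spec$covariance)) stop("mahalanobis requires a covariance matrix")
      R <- chol(spec$covariance)
      Z <- t(backsolve(R, t(D), transpose = TRUE))
      sqrt(rowSums(Z^2))
    })
}

#' Ledoit-style shrinkage covariance of embeddings
#'
#' Sample covariance blended with a scaled identity,
#' `(1 - alpha) S + alpha (tr(S)/d) I`, guaranteeing positive-definiteness at
#' small sample sizes.
#'
#' @param embeddings `N x dim` matrix.
#' @param alpha shrinkage intensity in `(0, 1]`.
#' @return `dim x dim` positive-definite matrix.
#' @export
shrinkage_covariance <- function(embeddings, alpha = 0.1) {
  stopifnot(alpha > 0, alpha <= 1)
  S <- stats::cov(embeddings)
  d <- ncol(embeddings)
  (1 - alpha) * S + alpha * (sum(diag(S)) / d) * diag(d)
}

#' Verify whether a pair is the same individual
#'
#' Decision rule: `same` iff `d <= threshold` (a tie counts as same).
#'
#' @param d distance (>= 0); vectorized.
#' @param threshold decision threshold.
#' @return character vector in `c("same", "different")`.
#' @export
verify_pair <- function(d, threshold) {
  stopifnot(all(d >= 0))
  ifelse(d <= threshold, "same", "different")
}

#' Verification accuracy of a pair set at a threshold
#'
#' @param pairs a `pair_set` or a data frame with a `label` column.
#' @param distances one distance per pair.
#' @param threshold decision threshold.
#' @return fraction of pairs whose [verify_pair()] decision matches the label.
#' @export
pair_accuracy <- function(pairs, distances, threshold) {
  labels <- pair_labels(pairs)
  if (length(labels) != length(distances)) stop("one distance per pair required")
  mean(verify_pair(distances, threshold) == labels)
}

pair_labels <- function(pairs) {
  if (inherits(pairs, "pair_set")) pairs$pairs$label
  else if (is.data.frame(pairs)) pairs$label
  else as.character(pairs)
}

#' Exhaustive threshold search on the metric's grid
#'
#' Evaluates [pair_accuracy()] at every grid point `lower, lower + step, ...,
#' upper` of the metric's threshold range and returns the maximizer; ties are
#' broken toward the smallest qualifying threshold (the most conservative
#' acceptor).
#'
#' @param pairs labels (as in [pair_accuracy()]).
#' @param distances per-pair distances.
#' @param spec a [metric_spec()].
#' @return list with `threshold`, `accuracy`.
#' @export
threshold_search <- function(pairs, distances, spec) {
  labels <- pair_labels(pairs)
  if (length(labels) == 0L) stop("empty pair set")
  grid <- seq(spec$range[1L], spec$range[2L], by = spec$step)
  is_pos <- labels == "same"
  dp <- sort(distances[is_pos])
  dn <- sort(distances[!is_pos])
  # accuracy(t) = (#pos with d <= t) + (#neg with d > t), via sorted counts
  np <- findInterval(grid, dp)                 # d <= t (ties included)
  nn <- length(dn) - findInterval(grid, dn)
  acc <- (np + nn) / length(labels)
  best <- which.max(acc)                       # first max = smallest threshold
  list(threshold = grid[best], accuracy = acc[best])
}

#' Ten-fold cross-validated threshold calibration
#'
#' The pair set is partitioned into ten near-equal folds (seeded). For each
#' fold i, the threshold is searched exhaustively on the other nine folds and
#' the held-out accuracy at that threshold becomes `Acc_i`.
#'
#' @param pairs a `pair_set` (or label vector).
#' @param distances per-pair distances.
#' @param spec a [metric_spec()].
#' @param n_folds number of folds.
#' @param seed fold-assignment seed.
#' @return data frame with columns `fold`, `threshold` (d_i), `accuracy`
#'   (Acc_i, percent).
#' @export
tenfold_cv <- function(pairs, distances, spec, n_folds = 10L, seed = 1L) {
  labels <- pair_labels(pairs)
  n <- length(labels)
  if (n < n_folds) stop("need at least ", n_folds, " pairs for ", n_folds,
                        "-fold cross-validation")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  fold <- sample(rep_len(seq_len(n_folds), n))
  res <- lapply(seq_len(n_folds), function(i) {
    cal <- fold != i
    ts <- threshold_search(labels[cal], distances[cal], spec)
    data.frame(fold = i, threshold = ts$threshold,
               accuracy = 100 * pair_accuracy(labels[!cal],
                                              distances[!cal], ts$threshold))
  })
  do.call(rbind, res)
}

#' Accuracy-weighted optimal threshold
#'
#' `d_opt = sum(Acc_i * d_i) / sum(Acc_i)` over the cross-validation folds:
#' each fold's best threshold weighted by the accuracy it achieved.
#'
#' @param folds data frame with columns `threshold` and `accuracy`
#'   (as from [tenfold_cv()]).
#' @return scalar `d_opt`, always within `[min d_i, max d_i]`.
#' @export
aggregate_optimal_threshold <- function(folds) {
  stopifnot(all(c("threshold", "accuracy") %in% names(folds)))
  w <- folds$accuracy
  if (sum(w) == 0) stop("all fold accuracies are zero: weighted threshold undefined")
  sum(w * folds$threshold) / sum(w)
}

#' Mean cross-validated accuracy
#'
#' Arithmetic mean of the per-fold held-out accuracies, reported in percent
#' to two decimals.
#'
#' @param folds data frame with an `accuracy` column (percent).
#' @return scalar percent.
#' @export
mean_cv_accuracy <- function(folds) {
  round(mean(folds$accuracy), 2)
}

#' Closed-set top-k accuracy
#'
#' Top-1 is `TP / (TP + FN)`; top-5 is the fraction of samples whose true
#' label is among the five best-scored identities.
#'
#' @param scores `N x C` score matrix (higher = better) or, for `counts`
#'   input, a list with `tp`, `fn` (top-1) / `t5p`, `total` (top-5).
#' @param labels integer true labels in `1..C` (ignored for counts input).
#' @param k 1 or 5.
#' @return accuracy fraction.
#' @export
topk_accuracy <- function(scores, labels = NULL, k = 1L) {
  stopifnot(k %in% c(1L, 5L))
  if (is.list(scores) && !is.data.frame(scores) && is.null(dim(scores))) {
    if (k == 1L) {
      tot <- scores$tp + scores$fn
      if (tot == 0) stop("zero denominator in top-1 accuracy")
      return(scores$tp / tot)
    }
    if (is.null(scores$total) || scores$total == 0) {
      stop("zero denominator in top-5 accuracy")
    }
    return(scores$t5p / scores$total)
  }
  if (is.null(dim(scores))) scores <- matrix(scores, 1L)
  stopifnot(length(labels) == nrow(scores))
  hit <- vapply(seq_len(nrow(scores)), function(i) {
    ord <- order(scores[i, ], decreasing = TRUE)
    labels[i] %in% ord[seq_len(min(k, length(ord)))]
  }, logical(1))
  mean(hit)
}

#' Calibrate a verification threshold on embeddings and pairs
#'
#' Runs the full open-set calibration: per-pair distances, ten-fold
#' cross-validated threshold search, Eq-style accuracy-weighted threshold
#' aggregation and the mean cross-validated accuracy. For the mahalanobis
#' metric the covariance is estimated (with shrinkage) from the embeddings of
#' the calibration folds of each split.
#'
#' @param embeddings `N x dim` matrix (row i = embedding of test image i).
#' @param pairs a `pair_set` over those images.
#' @param metric metric name (see [metric_spec()]).
#' @param n_folds,seed cross-validation controls.
#' @param shrinkage mahalanobis covariance shrinkage intensity.
#' @return a `calibration_report`: list with `metric`, `folds` (data frame),
#'   `d_opt`, `mean_accuracy`.
#' @export
calibrate <- function(embeddings, pairs, metric = "cosine", n_folds = 10L,
                      seed = 1L, shrinkage = 0.1) {
  if (metric == "mahalanobis") {
    n <- nrow(pairs$pairs)
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    fold <- sample(rep_len(seq_len(n_folds), n))
    res <- lapply(seq_len(n_folds), function(i) {
      cal <- fold != i
      cal_imgs <- unique(c(pairs$pairs$a[cal], pairs$pairs$b[cal]))
      spec <- metric_spec("mahalanobis",
                          covariance = shrinkage_covariance(
                            embeddings[cal_imgs, , drop = FALSE], shrinkage))
      dists <- pair_distances(embeddings, pairs$pairs, spec)
      ts <- threshold_search(pairs$pairs$label[cal], dists[cal], spec)
      data.frame(fold = i, threshold = ts$threshold,
                 accuracy = 100 * pair_accuracy(pairs$pairs$label[!cal],
                                                dists[!cal], ts$threshold))
    })
    folds <- do.call(rbind, res)
  } else {
    spec <- metric_spec(metric)
    dists <- pair_distances(embeddings, pairs$pairs, spec)
    folds <- tenfold_cv(pairs, dists, spec, n_folds, seed)
  }
  structure(list(metric = metric, folds = folds,
                 d_opt = aggregate_optimal_threshold(folds),
                 mean_accuracy = mean_cv_accuracy(folds)),
            class = "calibration_report")
}

#' @export
print.calibration_report <- function(x, ...) {
  cat("Ten-fold verification calibration —", x$metric, "distance\n")
  print(x$folds, row.names = FALSE)
  cat(sprintf("d_opt (accuracy-weighted): %.4f\n", x$d_opt))
  cat(sprintf("mean accuracy: %.2f%%\n", x$mean_accuracy))
  invisible(x)
}
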