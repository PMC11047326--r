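# Open-set verification: distance metrics and their axioms, the tie rule,
# exhaustive threshold search against brute-force oracles, ten-fold
# calibration and the accuracy-weighted threshold aggregation.

test_that("distance metrics match their definitions on canonical inputs", {
  f <- c(0.3, -1.2, 4)
  for (m in c("euclidean", "cosine", "manhattan")) {
    expect_equal(distance(f, f, metric_spec(m)), 0, tolerance = 1e-12)
  }
  expect_equal(distance(f, f, metric_spec("mahalanobis",
                                          covariance = diag(3))), 0)
  e1 <- c(1, 0); e2 <- c(0, 1)
  expect_equal(distance(e1, e2, metric_spec("euclidean")), sqrt(2))
  expect_equal(distance(e1, e2, metric_spec("cosine")), 1)
  expect_equal(distance(e1, e2, metric_spec("manhattan")), 2)
  expect_error(distance(c(0, 0), e2, metric_spec("cosine")), "zero-norm")
  expect_error(metric_spec("mahalanobis",
                           covariance = matrix(c(1, 2, 2, 1), 2)),
               "positive-definite")
})

test_that("mahalanobis with identity covariance equals euclidean", {
  set.seed(15)
  spec_m <- metric_spec("mahalanobis", covariance = diag(6))
  spec_e <- metric_spec("euclidean")
  for (i in 1:100) {
    a <- rnorm(6); b <- rnorm(6)
    expect_equal(distance(a, b, spec_m), distance(a, b, spec_e),
                 tolerance = 1e-8)
  }
})

test_that("metric axioms hold numerically", {
  set.seed(16)
  specs <- list(metric_spec("euclidean"), metric_spec("manhattan"),
                metric_spec("mahalanobis",
                            covariance = shrinkage_covariance(
                              matrix(rnorm(200), 50, 4))),
                metric_spec("cosine"))
  for (i in 1:50) {
    a <- rnorm(4); b <- rnorm(4); c <- rnorm(4)
    for (sp in specs) {
      expect_gte(distance(a, b, sp), 0)
      expect_equal(distance(a, b, sp), distance(b, a, sp), tolerance = 1e-12)
      if (sp$name != "cosine") {
        expect_lte(distance(a, c, sp),
                   distance(a, b, sp) + distance(b, c, sp) + 1e-12)
      }
    }
  }
})

test_that("pair verification uses d <= threshold with ties counted as same", {
  expect_equal(verify_pair(0, 0), "same")
  expect_equal(verify_pair(5, 2), "different")
  expect_equal(verify_pair(2, 2), "same")
})

test_that("pair accuracy agrees with an exhaustive per-pair loop", {
  set.seed(17)
  labels <- sample(c("same", "different"), 40, replace = TRUE)
  d <- runif(40)
  for (t in c(0, 0.25, 0.5, 1)) {
    manual <- mean(vapply(seq_along(d), function(i) {
      dec <- if (d[i] <= t) "same" else "different"
      dec == labels[i]
    }, logical(1)))
    expect_equal(pair_accuracy(labels, d, t), manual)
  }
  # perfectly separated balanced set
  lab <- rep(c("same", "different"), each = 5)
  dd <- c(rep(0.1, 5), rep(0.9, 5))
  expect_equal(pair_accuracy(lab, dd, 0.5), 1)
  # threshold 0 with positive distances: only negatives are correct
  expect_equal(pair_accuracy(lab, dd, 0), 0.5)
  expect_error(pair_accuracy(lab, dd[1:3], 0.5), "one distance per pair")
})

test_that("threshold search scans the grid and breaks ties to the smallest", {
  lab <- c("same", "same", "different", "different")
  d <- c(0.1, 0.2, 0.5, 0.6)
  r <- threshold_search(lab, d, metric_spec("cosine"))
  expect_equal(r$accuracy, 1)
  expect_equal(r$threshold, 0.2)   # first grid point reaching 100%
  # all-identical distances: balanced set cannot exceed 0.5; smallest
  # threshold (the grid lower bound) wins the tie
  r2 <- threshold_search(rep(c("same", "different"), 5), rep(0.3, 10),
                         metric_spec("cosine"))
  expect_equal(r2$accuracy, 0.5)
  expect_equal(r2$threshold, 0)
  expect_error(threshold_search(character(0), numeric(0),
                                metric_spec("cosine")), "empty")
})

test_that("grid search equals a sorted-scan oracle on random instances", {
  # oracle: best split over candidate cuts at each sorted distance
  oracle <- function(labels, d, grid) {
    best_acc <- -1; best_t <- NA
    for (t in grid) {
      acc <- mean(ifelse(d <= t, "same", "different") == labels)
      if (acc > best_acc) { best_acc <- acc; best_t <- t }
    }
    list(threshold = best_t, accuracy = best_acc)
  }
  set.seed(18)
  spec <- metric_spec("cosine")
  for (i in 1:100) {
    n <- sample(6:20, 1)
    labels <- sample(c("same", "different"), n, replace = TRUE)
    # distances on grid points so the optimal cut lies on the grid
    d <- round(runif(n), 4)
    r <- threshold_search(labels, d, spec)
    o <- oracle(labels, d, seq(0, 1, by = 1e-4))
    expect_equal(r$accuracy, o$accuracy)
    expect_equal(r$threshold, o$threshold)
    # never exceeds the unconstrained optimum from sorting distances
    cuts <- c(0, sort(unique(d)))
    unconstrained <- max(vapply(cuts, function(t)
      mean(ifelse(d <= t, "same", "different") == labels), numeric(1)))
    expect_lte(r$accuracy, unconstrained + 1e-12)
  }
})

test_that("ten-fold cross-validation partitions pairs and is deterministic", {
  # two point masses: every calibration threshold transfers exactly
  labels <- rep(c("same", "different"), each = 30)
  d <- rep(c(0.1, 0.9), each = 30)
  spec <- metric_spec("cosine")
  folds <- tenfold_cv(labels, d, spec, seed = 5L)
  expect_equal(nrow(folds), 10L)
  expect_equal(folds$accuracy, rep(100, 10))  # perfectly separable
  expect_identical(folds, tenfold_cv(labels, d, spec, seed = 5L))
  expect_error(tenfold_cv(labels[1:5], d[1:5], spec), "at least 10")
  # each pair held out exactly once: fold sizes sum to n and are near-equal
  set.seed(5L)
  fold <- sample(rep_len(1:10, 60))
  expect_equal(sort(unique(fold)), 1:10)
  expect_true(all(table(fold) == 6))
})

test_that("the accuracy-weighted optimal threshold follows its formula", {
  # constant thresholds: any accuracies give back the constant
  folds <- data.frame(threshold = rep(2.45, 10),
                      accuracy = runif(10, 80, 100))
  expect_equal(aggregate_optimal_threshold(folds), 2.45)
  # equal accuracies reduce to the simple mean
  folds2 <- data.frame(threshold = 1:10, accuracy = rep(93, 10))
  expect_equal(aggregate_optimal_threshold(folds2), mean(1:10))
  # hand-computed two-fold case
  folds3 <- data.frame(threshold = c(1, 3), accuracy = c(0.25, 0.75))
  expect_equal(aggregate_optimal_threshold(folds3), 2.5)
  expect_error(aggregate_optimal_threshold(
    data.frame(threshold = c(1, 2), accuracy = c(0, 0))), "zero")
})

test_that("d_opt always lies within the fold threshold range", {
  set.seed(20)
  for (i in 1:50) {
    folds <- data.frame(threshold = runif(10, 0, 5),
                        accuracy = runif(10, 1, 100))
    d_opt <- aggregate_optimal_threshold(folds)
    expect_gte(d_opt, min(folds$threshold))
    expect_lte(d_opt, max(folds$threshold))
  }
})

test_that("top-k accuracy follows its definitions", {
  expect_equal(topk_accuracy(list(tp = 3, fn = 1), k = 1L), 0.75)
  expect_error(topk_accuracy(list(tp = 0, fn = 0), k = 1L), "denominator")
  # every true label ranked first
  sc <- diag(6) + 0.01
  expect_equal(topk_accuracy(sc, 1:6, 1L), 1)
  expect_equal(topk_accuracy(sc, 1:6, 5L), 1)
  # top-5 >= top-1 on any ranked set
  set.seed(21)
  sc2 <- matrix(rnorm(40 * 8), 40, 8)
  lb <- sample(1:8, 40, replace = TRUE)
  expect_gte(topk_accuracy(sc2, lb, 5L), topk_accuracy(sc2, lb, 1L))
})

test_that("random rankings over 62 classes give top-5 near 5/62", {
  set.seed(22)
  n <- 4000L
  sc <- matrix(rnorm(n * 62), n, 62)
  lb <- sample(1:62, n, replace = TRUE)
  expect_equal(topk_accuracy(sc, lb, 5L), 5 / 62, tolerance = 0.15)
})

test_that("calibration separates separable embeddings and not random ones", {
  se <- separable_embeddings(n_ids = 4L, per_id = 12L, seed = 30)
  ps <- pairs_from_labels(se$labels, 60L, 60L, seed = 2L)
  rep <- calibrate(se$embeddings, ps, metric = "cosine", seed = 2L)
  # the conservative smallest-threshold tie rule can miss a borderline
  # held-out positive, so near-perfect rather than exactly 100
  expect_gte(rep$mean_accuracy, 98)
  expect_gte(rep$d_opt, 0)
  expect_lte(rep$d_opt, 1)
  # random embeddings with random labels: chance level on balanced pairs
  set.seed(31)
  E <- matrix(rnorm(48 * 8), 48, 8)
  rep0 <- calibrate(E, ps, metric = "cosine", seed = 2L)
  expect_lt(abs(rep0$mean_accuracy - 50), 15)
  # mahalanobis path estimates a per-fold shrinkage covariance
  repm <- calibrate(se$embeddings, ps, metric = "mahalanobis", seed = 2L)
  expect_gte(repm$mean_accuracy, 95)
})

test_that("bundled reference folds reproduce the published aggregates", {
  folds <- reference_calibration_folds("cosine")
  expect_equal(nrow(folds), 10L)
  expect_equal(mean_cv_accuracy(folds), 94.58)
  expect_equal(aggregate_optimal_threshold(folds), 0.0047)
  expect_equal(mean_cv_accuracy(reference_calibration_folds("euclidean")),
               92.90)
  expect_equal(mean_cv_accuracy(reference_calibration_folds("manhattan")),
               93.46)
})
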