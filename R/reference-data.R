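# Bundled reference results from the published 70-cow overhead study this
# package's protocol follows. They are inputs for validating the aggregation
# arithmetic (weighted optimal thresholds, mean cross-validated accuracy,
# augmentation/STN accuracy deltas) — not outputs of this package.

#' Reference ten-fold calibration results
#'
#' Per-fold optimal verification thresholds and held-out accuracies reported
#' for a 70-cow overhead Holstein dataset (8 held-out test identities, 273
#' positive + 273 negative pairs), for all four distance metrics. Applying
#' [aggregate_optimal_threshold()] and [mean_cv_accuracy()] to these folds
#' reproduces the published optimal thresholds (2.45 euclidean, 0.0047
#' cosine, 4.24 mahalanobis, 72.2 manhattan) and average accuracies (92.90,
#' 94.58, 92.90, 93.46 percent).
#'
#' @param metric optional metric name to filter to one column.
#' @return data frame with columns `metric`, `fold`, `threshold`, `accuracy`.
#' @export
reference_calibration_folds <- function(metric = NULL) {
  df <- utils::read.csv(system.file("extdata",
                                    "reference_calibration_folds.csv",
                                    package = "cowreid"))
  if (!is.null(metric)) {
    stopifnot(metric %in% df$metric)
    df <- df[df$metric == metric, ]
    rownames(df) <- NULL
  }
  df
}

#' Reference recognition accuracy under lighting and visibility conditions
#'
#' Published verification accuracies (percent) of three model variants —
#' the full model with dataloader augmentation (`ResSTN`), the same model
#' without augmentation (`ResSTN-NE`), and the backbone without the spatial
#' transformer or augmentation (`ResNet101-NE`) — on six test conditions:
#' full-body, randomly cropped and randomly occluded images under natural and
#' artificial lighting. Differences across these cells quantify the
#' contribution of the spatial transformer (mean 2.98 percentage points) and
#' of crop/occlusion augmentation (2.61 and 1.91 points under natural light).
#'
#' @return data frame with columns `model`, `lighting`, `condition`,
#'   `accuracy`.
#' @export
reference_condition_accuracy <- function() {
  utils::read.csv(system.file("extdata", "reference_condition_accuracy.csv",
                              package = "cowreid"))
}
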