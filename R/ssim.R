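# Structural similarity and near-duplicate frame removal.

# Separable Gaussian filtering with reflect padding (radius = (win-1)/2).
gauss_filter <- function(m, sigma = 1.5, win = 11L) {
  r <- (win - 1L) %/% 2L
  kk <- exp(-0.5 * ((-r:r) / sigma)^2)
  kk <- kk / sum(kk)
  reflect_idx <- function(n) c(r:1, seq_len(n), n - seq_len(r) + 1L)
  mp <- m[reflect_idx(nrow(m)), reflect_idx(ncol(m)), drop = FALSE]
  # filter columns then rows
  out <- matrix(0, nrow(m) + 2L * r, ncol(m))
  for (t in seq_len(win)) {
    out <- out + kk[t] * mp[, t:(t + ncol(m) - 1L), drop = FALSE]
  }
  out2 <- matrix(0, nrow(m), ncol(m))
  for (t in seq_len(win)) {
    out2 <- out2 + kk[t] * out[t:(t + nrow(m) - 1L), , drop = FALSE]
  }
  out2
}

#' Structural similarity index between two images
#'
#' Gaussian-weighted SSIM (11x11 window, sigma 1.5) with the conventional
#' stabilizing constants `C1 = (0.01 L)^2`, `C2 = (0.03 L)^2`; the local SSIM
#' map is averaged over the window-valid interior. Symmetric in its
#' arguments; bounded by `[-1, 1]`; exactly 1 for identical images.
#'
#' @param image_a,image_b numeric matrices of identical dimensions
#'   (grayscale; `labeled_image` objects are accepted).
#' @param data_range dynamic range L of the pixel values (1 for `[0, 1]`).
#' @return scalar SSIM score.
#' @export
ssim <- function(image_a, image_b, data_range = 1) {
  if (inherits(image_a, "labeled_image")) image_a <- image_a$pixels
  if (inherits(image_b, "labeled_image")) image_b <- image_b$pixels
  if (!all(dim(image_a) == dim(image_b))) {
    stop("images must have identical dimensions")
  }
  win <- 11L
  if (any(dim(image_a) < win)) stop("images smaller than the 11x11 SSIM window")
  C1 <- (0.01 * data_range)^2
  C2 <- (0.03 * data_range)^2
  mu1 <- gauss_filter(image_a)
  mu2 <- gauss_filter(image_b)
  s11 <- gauss_filter(image_a * image_a) - mu1^2
  s22 <- gauss_filter(image_b * image_b) - mu2^2
  s12 <- gauss_filter(image_a * image_b) - mu1 * mu2
  map <- ((2 * mu1 * mu2 + C1) * (2 * s12 + C2)) /
    ((mu1^2 + mu2^2 + C1) * (s11 + s22 + C2))
  r <- (win - 1L) %/% 2L
  core <- map[(r + 1L):(nrow(map) - r), (r + 1L):(ncol(map) - r)]
  mean(core)
}

#' Drop near-duplicate frames by streaming SSIM
#'
#' Scanning the list in order, an image is dropped when its SSIM against the
#' most recently *retained* image exceeds the threshold (strict inequality);
#' the first image is always retained. This targets the adjacent-frame
#' redundancy of video-extracted stills; 0.78 is the curation threshold used
#' for the overhead-cattle footage this generator emulates.
#'
#' @param images ordered list of images (matrices or `labeled_image`).
#' @param threshold SSIM threshold in `[0, 1]`.
#' @return the retained sublist (empty input gives an empty list).
#' @export
dedup_by_ssim <- function(images, threshold = 0.78) {
  stopifnot(threshold >= 0, threshold <= 1)
  if (length(images) == 0L) return(list())
  keep <- 1L
  last <- 1L
  for (i in seq_along(images)[-1L]) {
    if (ssim(images[[i]], images[[last]]) <= threshold) {
      keep <- c(keep, i)
      last <- i
    }
  }
  images[keep]
}
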