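# Dataloader-stage preprocessing: orientation normalization by aspect ratio,
# stochastic augmentation (training only by default), and bilinear resize.

#' Orientation normalization by aspect ratio
#'
#' With `AspectRatio = w/h`: images with `w/h >= 1` pass through unchanged
#' (this includes squares); images with `w/h < 1` are rotated 90 degrees
#' clockwise, so the output aspect ratio is always >= 1. Idempotent.
#'
#' @param image numeric matrix (H x W) or `labeled_image`.
#' @return same type as the input.
#' @export
aspect_ratio_rotation <- function(image) {
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  if (ncol(px) / nrow(px) >= 1) return(image)
  rot <- t(px[nrow(px):1L, , drop = FALSE])  # 90 degrees clockwise
  if (inherits(image, "labeled_image")) {
    image$pixels <- rot
    image
  } else {
    rot
  }
}

#' Stochastic augmentation policy
#'
#' @param p_flip probability of a flip (horizontal or vertical, chosen
#'   uniformly).
#' @param p_crop_width,p_crop_height probability of removing `crop_fraction`
#'   of the width/height from one uniformly chosen side.
#' @param p_occlude probability of painting one rectangle with height and
#'   width drawn uniformly from `occ_min:occ_max` pixels at a uniform
#'   position.
#' @param occ_min,occ_max occlusion size bounds in pixels.
#' @param crop_fraction fraction of the side removed by each crop.
#' @param fill occlusion fill value (solid black by default, emulating
#'   camera soiling; set to `NA` for a random gray per occlusion).
#' @return an `augment_config` list.
#' @export
augment_config <- function(p_flip = 0.5, p_crop_width = 0.3,
                           p_crop_height = 0.3, p_occlude = 0.3,
                           occ_min = 10L, occ_max = 18L,
                           crop_fraction = 1 / 3, fill = 0) {
  probs <- c(p_flip, p_crop_width, p_crop_height, p_occlude)
  stopifnot(all(probs >= 0), all(probs <= 1), occ_min <= occ_max,
            crop_fraction > 0, crop_fraction < 1)
  structure(list(p_flip = p_flip, p_crop_width = p_crop_width,
                 p_crop_height = p_crop_height, p_occlude = p_occlude,
                 occ_min = as.integer(occ_min), occ_max = as.integer(occ_max),
                 crop_fraction = crop_fraction, fill = fill),
            class = "augment_config")
}

#' Apply the stochastic augmentation policy to one image
#'
#' Transforms are applied independently, in fixed order
#' flip -> width-crop -> height-crop -> occlusion, each firing with its
#' configured probability. Fully determined by `seed`. If the image (after
#' any crops) is smaller than the occlusion rectangle bounds, the occlusion
#' is skipped with a warning.
#'
#' @param image numeric matrix or `labeled_image`.
#' @param config from [augment_config()].
#' @param seed integer seed.
#' @return augmented image (same type as input).
#' @export
augment <- function(image, config = augment_config(), seed = 1L) {
  stopifnot(inherits(config, "augment_config"))
  px <- if (inherits(image, "labeled_image")) image$pixels else image
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (stats::runif(1) < config$p_flip) {
    if (stats::runif(1) < 0.5) {
      px <- px[, ncol(px):1L, drop = FALSE]   # horizontal
    } else {
      px <- px[nrow(px):1L, , drop = FALSE]   # vertical
    }
  }
  if (stats::runif(1) < config$p_crop_width) {
    side <- if (stats::runif(1) < 0.5) "left" else "right"
    px <- crop_side(px, side, config$crop_fraction)
  }
  if (stats::runif(1) < config$p_crop_height) {
    side <- if (stats::runif(1) < 0.5) "top" else "bottom"
    px <- crop_side(px, side, config$crop_fraction)
  }
  if (stats::runif(1) < config$p_occlude) {
    if (nrow(px) <= config$occ_max || ncol(px) <= config$occ_max) {
      warning("image smaller than occlusion bounds after cropping; occlusion skipped")
    } else {
      oh <- sample(config$occ_min:config$occ_max, 1L)
      ow <- sample(config$occ_min:config$occ_max, 1L)
      top <- sample.int(nrow(px) - oh + 1L, 1L)
      left <- sample.int(ncol(px) - ow + 1L, 1L)
      fill <- if (is.na(config$fill)) stats::runif(1) else config$fill
      px[top:(top + oh - 1L), left:(left + ow - 1L)] <- fill
    }
  }
  if (inherits(image, "labeled_image")) {
    image$pixels <- px
    image
  } else {
    px
  }
}

#' Bilinear image resize
#'
#' @param image numeric matrix.
#' @param height,width target dimensions.
#' @return resized matrix.
#' @export
resize_bilinear <- function(image, height, width) {
  if (inherits(image, "labeled_image")) image <- image$pixels
  g <- grid_generator(matrix(c(1, 0, 0, 0, 1, 0), 2L, 3L, byrow = TRUE),
                      c(height, width))
  out <- bilinear_sample(array(image, c(1L, dim(image))), g)
  matrix(out, height, width)
}

# Dataloader transform: orientation normalization, optional augmentation,
# resize to the network input size. Returns a plain matrix.
preprocess_image <- function(image, input_size, augment_cfg = NULL,
                             seed = 1L) {
  im <- aspect_ratio_rotation(image)
  if (!is.null(augment_cfg)) im <- augment(im, augment_cfg, seed)
  px <- if (inherits(im, "labeled_image")) im$pixels else im
  resize_bilinear(px, input_size, input_size)
}
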