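# Synthetic overhead coat-pattern imagery.
#
# The generator stands in for a private farm dataset: each identity is a
# Holstein-like dorsal pattern — black ellipsoidal blobs on a white body over
# a mid-gray background — rendered at uniform random orientation under one of
# two lighting regimes (bright/clean "natural" vs. darkened "artificial" with
# a soft shadow band), optionally side-cropped or partially occluded. Blobs
# are evaluated analytically in the rotated body frame, so rendering is exact
# at any angle and bit-reproducible from (identity, seed, config).

#' Pattern generator configuration
#'
#' @param blob_count_range integer range (min, max) of blobs per identity;
#'   `c(0, 0)` produces deliberately "low-feature" identities, the known
#'   failure mode for pattern-based recognition.
#' @param radius_range blob radius range, as a fraction of body length.
#' @param ecc_range blob eccentricity range (1 = circular).
#' @param body_aspect_range body length-to-width ratio range (> 1).
#' @return a `pattern_config` list.
#' @export
pattern_config <- function(blob_count_range = c(4L, 9L),
                           radius_range = c(0.05, 0.14),
                           ecc_range = c(1, 3),
                           body_aspect_range = c(2.0, 2.6)) {
  if (length(blob_count_range) != 2L || blob_count_range[1L] < 0 ||
      blob_count_range[2L] < blob_count_range[1L]) {
    stop("invalid blob-count range: need 0 <= min <= max")
  }
  stopifnot(all(body_aspect_range > 1), all(ecc_range >= 1),
            all(radius_range > 0))
  structure(list(blob_count_range = as.integer(blob_count_range),
                 radius_range = radius_range, ecc_range = ecc_range,
                 body_aspect_range = body_aspect_range),
            class = "pattern_config")
}

#' Generate the coat-pattern template of one identity
#'
#' A template is a pure function of `(identity_id, seed, config)`: the same
#' arguments always reproduce it bit-for-bit, and distinct identities under
#' the same seed get distinct blob sets with probability 1.
#'
#' @param identity_id integer identity label (>= 0).
#' @param seed integer master seed.
#' @param config from [pattern_config()].
#' @return a `coat_template` with fields `identity_id`, `seed`, `blob_set`
#'   (data frame: `cx`, `cy` in the canonical body frame, `radius`, `ecc`),
#'   `body_aspect`, and `low_feature`.
#' @export
generate_identity <- function(identity_id, seed, config = pattern_config()) {
  stopifnot(is.numeric(identity_id), identity_id >= 0, is.numeric(seed),
            inherits(config, "pattern_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(((as.integer(seed) %% 59999L) * 30011L +
              as.integer(identity_id) * 101L + 17L) %% .Machine$integer.max)
  aspect <- stats::runif(1, config$body_aspect_range[1L],
                         config$body_aspect_range[2L])
  n_blob <- if (config$blob_count_range[2L] == 0L) 0L else
    sample(seq(config$blob_count_range[1L], config$blob_count_range[2L]), 1L)
  if (n_blob > 0L) {
    # rejection-sample centers inside the canonical body ellipse
    # (semi-axes 0.5 and 0.5/aspect, shrunk so blobs stay on the body)
    cx <- numeric(0); cy <- numeric(0)
    while (length(cx) < n_blob) {
      px <- stats::runif(n_blob, 0, 1)
      py <- stats::runif(n_blob, 0.5 - 0.5 / aspect, 0.5 + 0.5 / aspect)
      q <- ((px - 0.5) / 0.42)^2 + ((py - 0.5) / (0.42 / aspect))^2
      cx <- c(cx, px[q <= 1]); cy <- c(cy, py[q <= 1])
    }
    blob_set <- data.frame(
      cx = cx[seq_len(n_blob)], cy = cy[seq_len(n_blob)],
      radius = stats::runif(n_blob, config$radius_range[1L],
                            config$radius_range[2L]),
      ecc = stats::runif(n_blob, config$ecc_range[1L], config$ecc_range[2L]))
  } else {
    blob_set <- data.frame(cx = numeric(0), cy = numeric(0),
                           radius = numeric(0), ecc = numeric(0))
  }
  structure(list(identity_id = as.integer(identity_id),
                 seed = as.integer(seed), blob_set = blob_set,
                 body_aspect = aspect, low_feature = n_blob == 0L),
            class = "coat_template")
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Rendering specification for one image instance
#'
#' @param orientation_deg body orientation in degrees `[0, 360)`, clockwise.
#' @param lighting `"natural"` (bright, clean) or `"artificial"` (global
#'   brightness times `brightness`, plus one soft-edged shadow band).
#' @param shadow_strength shadow darkening fraction in `[0, 1]`; must be 0
#'   under natural lighting and > 0 under artificial lighting.
#' @param brightness global multiplier under artificial lighting (< 1).
#' @param crop_fraction fraction (at most 1/3) of one side removed.
#' @param occlusion_rect optional `c(x, y, w, h)` rectangle (pixels, x = column)
#'   painted over the image.
#' @param noise_seed integer seed for the per-instance randomness (shadow
#'   geometry, crop side, pixel noise).
#' @param canvas `c(height, width)` in pixels (>= 32 each).
#' @param noise_sd standard deviation of additive pixel noise (0 disables).
#' @return a `render_spec` list.
#' @export
render_spec <- function(orientation_deg = 0, lighting = c("natural", "artificial"),
                        shadow_strength = NULL, brightness = 0.6,
                        crop_fraction = 0, occlusion_rect = NULL,
                        noise_seed = 0L, canvas = c(224L, 160L),
                        noise_sd = 0.01) {
  lighting <- match.arg(lighting)
  if (is.null(shadow_strength)) {
    shadow_strength <- if (lighting == "artificial") 0.5 else 0
  }
  if (lighting == "natural" && shadow_strength != 0) {
    stop("natural lighting implies shadow_strength = 0")
  }
  if (lighting == "artificial" && (shadow_strength <= 0 || brightness >= 1)) {
    stop("artificial lighting implies brightness < 1 and shadow_strength > 0")
  }
  stopifnot(orientation_deg >= 0, orientation_deg < 360,
            crop_fraction >= 0, crop_fraction <= 1 / 3 + 1e-9,
            length(canvas) == 2L, all(canvas >= 32L))
  structure(list(orientation_deg = orientation_deg, lighting = lighting,
                 shadow_strength = shadow_strength, brightness = brightness,
                 crop_fraction = crop_fraction, occlusion_rect = occlusion_rect,
                 noise_seed = as.integer(noise_seed),
                 canvas = as.integer(canvas), noise_sd = noise_sd),
            class = "render_spec")
}

#' Render one labelled image instance of a template
#'
#' The body and its blobs are rotated by `orientation_deg` about the canvas
#' center (the body is scaled to fit the canvas at its orientation), lighting
#' and optional crop/occlusion applied, and the identity plus all rendering
#' provenance recorded.
#'
#' @param template from [generate_identity()].
#' @param spec from [render_spec()].
#' @return a `labeled_image`: list with `pixels` (H x W matrix in `[0, 1]`),
#'   `identity`, and `provenance`.
#' @export
render_instance <- function(template, spec = render_spec()) {
  stopifnot(inherits(template, "coat_template"), inherits(spec, "render_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$noise_seed %% .Machine$integer.max)
  h <- spec$canvas[1L]; w <- spec$canvas[2L]
  phi <- spec$orientation_deg * pi / 180
  cphi <- cos(phi); sphi <- sin(phi)
  aspect <- template$body_aspect
  # body semi-axes (px): largest 'a' whose rotated extent fits in the canvas
  a <- 0.46 * min(w / (abs(cphi) + abs(sphi) / aspect),
                  h / (abs(sphi) + abs(cphi) / aspect))
  b <- a / aspect
  cx0 <- (w + 1) / 2; cy0 <- (h + 1) / 2
  X <- matrix(seq_len(w), h, w, byrow = TRUE) - cx0
  Y <- matrix(seq_len(h), h, w) - cy0
  # inverse (clockwise) rotation into the body frame
  xb <- cphi * X + sphi * Y
  yb <- -sphi * X + cphi * Y
  soft <- 1.5 # px, anti-aliasing band
  qbody <- sqrt((xb / a)^2 + (yb / b)^2)
  body_alpha <- pmin(1, pmax(0, (1 - qbody) * a / soft + 0.5))
  blob_alpha <- matrix(0, h, w)
  if (nrow(template$blob_set) > 0L) {
    for (i in seq_len(nrow(template$blob_set))) {
      bs <- template$blob_set[i, ]
      ox <- (bs$cx - 0.5) * 2 * a
      oy <- (bs$cy - 0.5) * 2 * a
      ra <- bs$radius * 2 * a * sqrt(bs$ecc)
      rb <- bs$radius * 2 * a / sqrt(bs$ecc)
      qb <- sqrt(((xb - ox) / ra)^2 + ((yb - oy) / rb)^2)
      blob_alpha <- pmax(blob_alpha, pmin(1, pmax(0, (1 - qb) * rb / soft + 0.5)))
    }
  }
  body_col <- 0.95 * (1 - blob_alpha) + 0.08 * blob_alpha
  img <- 0.5 * (1 - body_alpha) + body_col * body_alpha
  if (spec$lighting == "artificial") {
    img <- img * spec$brightness
    # one soft-edged dark band with random direction/offset/width
    psi <- stats::runif(1, 0, pi)
    off <- stats::runif(1, -0.25, 0.25) * min(h, w)
    bw <- stats::runif(1, 0.15, 0.3) * min(h, w)
    tproj <- cos(psi) * X + sin(psi) * Y
    band <- pmin(1, pmax(0, (bw / 2 + 6 - abs(tproj - off)) / 6))
    img <- img * (1 - spec$shadow_strength * band)
  }
  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(h * w, sd = spec$noise_sd), h, w)
  }
  img <- matrix(pmin(1, pmax(0, img)), h, w)  # pmax with a scalar drops dim
  if (spec$crop_fraction > 0) {
    side <- sample(c("left", "right", "top", "bottom"), 1L)
    img <- crop_side(img, side, spec$crop_fraction)
  }
  if (!is.null(spec$occlusion_rect)) {
    r <- spec$occlusion_rect
    if (r[1L] < 1 || r[2L] < 1 || r[1L] + r[3L] - 1 > ncol(img) ||
        r[2L] + r[4L] - 1 > nrow(img)) {
      stop("occlusion_rect outside canvas")
    }
    img[r[2L]:(r[2L] + r[4L] - 1), r[1L]:(r[1L] + r[3L] - 1)] <- 0
  }
  structure(list(pixels = img, identity = template$identity_id,
                 provenance = list(orientation_deg = spec$orientation_deg,
                                   lighting = spec$lighting,
                                   shadow_strength = spec$shadow_strength,
                                   crop_fraction = spec$crop_fraction,
                                   occluded = !is.null(spec$occlusion_rect),
                                   noise_seed = spec$noise_seed)),
            class = "labeled_image")
}

crop_side <- function(img, side, fraction) {
  h <- nrow(img); w <- ncol(img)
  switch(side,
         left = img[, (floor(w * fraction) + 1L):w, drop = FALSE],
         right = img[, seq_len(w - floor(w * fraction)), drop = FALSE],
         top = img[(floor(h * fraction) + 1L):h, , drop = FALSE],
         bottom = img[seq_len(h - floor(h * fraction)), , drop = FALSE])
}

#' Generate an identity-disjoint open-set dataset
#'
#' Training identities are split 8:2 into train/validation images (rounding
#' toward train); test identities are disjoint from them (the open-set
#' property) and contribute all their images to the test set. Lighting is
#' assigned per identity — roughly two thirds of training identities and
#' exactly half of the test identities are "natural" — matching a barn where
#' each animal is filmed under one regime.
#'
#' @param n_train_ids,n_test_ids identity counts (test >= 1 or open-set
#'   evaluation is impossible).
#' @param images_per_id renders per identity (>= 2).
#' @param seed master seed; the whole dataset is a pure function of it.
#' @param config from [pattern_config()].
#' @param canvas passed to [render_spec()].
#' @param noise_sd passed to [render_spec()].
#' @return a `dataset_split`: lists `train`, `val`, `test` of
#'   [render_instance()] images plus `identity_partition`.
#' @export
generate_dataset <- function(n_train_ids, n_test_ids, images_per_id, seed = 1L,
                             config = pattern_config(),
                             canvas = c(224L, 160L), noise_sd = 0.01) {
  if (n_test_ids < 1L) stop("n_test_ids must be >= 1: open-set evaluation is impossible without held-out identities")
  stopifnot(n_train_ids >= 1L, images_per_id >= 2L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  ids_train <- seq_len(n_train_ids) - 1L
  ids_test <- n_train_ids + seq_len(n_test_ids) - 1L
  light_train <- ifelse(stats::runif(n_train_ids) < 41 / 62,
                        "natural", "artificial")
  light_test <- rep(c("natural", "artificial"), length.out = n_test_ids)
  render_id <- function(id, lighting) {
    tpl <- generate_identity(id, seed, config)
    lapply(seq_len(images_per_id), function(i) {
      sp <- render_spec(
        orientation_deg = stats::runif(1, 0, 360),
        lighting = lighting,
        shadow_strength = if (lighting == "artificial")
          stats::runif(1, 0.3, 0.7) else 0,
        noise_seed = sample.int(.Machine$integer.max - 1L, 1L),
        canvas = canvas, noise_sd = noise_sd)
      render_instance(tpl, sp)
    })
  }
  train <- list(); val <- list(); test <- list()
  n_tr <- ceiling(0.8 * images_per_id)
  for (i in seq_along(ids_train)) {
    imgs <- render_id(ids_train[i], light_train[i])
    train <- c(train, imgs[seq_len(n_tr)])
    if (n_tr < images_per_id) val <- c(val, imgs[(n_tr + 1L):images_per_id])
  }
  for (i in seq_along(ids_test)) {
    test <- c(test, render_id(ids_test[i], light_test[i]))
  }
  partition <- c(stats::setNames(rep("train_val", n_train_ids),
                                 ids_train),
                 stats::setNames(rep("test", n_test_ids), ids_test))
  structure(list(train = train, val = val, test = test,
                 identity_partition = partition, seed = as.integer(seed)),
            class = "dataset_split")
}

#' Build balanced positive/negative verification pairs
#'
#' Positive pairs draw two distinct images of one identity; negative pairs
#' draw one image each from two different identities. Pairs are sampled
#' without replacement (no pair repeats, no image paired with itself) and the
#' set is balanced by construction.
#'
#' @param test_images list of `labeled_image` objects.
#' @param n_pos,n_neg pair counts; must be equal.
#' @param seed integer seed.
#' @return a `pair_set`: `pairs` (data frame `a`, `b` image indices and
#'   `label` in `same`/`different`), `n_positive`, `n_negative`.
#' @export
make_pairs <- function(test_images, n_pos, n_neg, seed = 1L) {
  if (n_pos != n_neg) stop("pair set must be balanced: n_pos must equal n_neg")
  labels <- vapply(test_images, function(im) im$identity, integer(1))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  tab <- table(labels)
  eligible <- as.integer(names(tab)[tab >= 2L])
  if (length(eligible) == 0L) stop("no identity with >= 2 images: cannot form positive pairs")
  pos_pool <- do.call(rbind, lapply(eligible, function(id) {
    idx <- which(labels == id)
    t(utils::combn(idx, 2L))
  }))
  if (nrow(pos_pool) < n_pos) {
    stop("requested ", n_pos, " positive pairs but only ", nrow(pos_pool),
         " distinct same-identity pairs exist")
  }
  pos <- pos_pool[sample.int(nrow(pos_pool), n_pos), , drop = FALSE]
  # negatives: sampled keys, without replacement of unordered pairs
  neg <- matrix(0L, 0L, 2L)
  seen <- character(0)
  n_img <- length(test_images)
  while (nrow(neg) < n_neg) {
    i <- sample.int(n_img, 1L)
    j <- sample.int(n_img, 1L)
    if (labels[i] == labels[j]) next
    key <- paste(min(i, j), max(i, j))
    if (key %in% seen) next
    seen <- c(seen, key)
    neg <- rbind(neg, c(i, j))
  }
  pairs <- data.frame(a = c(pos[, 1L], neg[, 1L]),
                      b = c(pos[, 2L], neg[, 2L]),
                      label = rep(c("same", "different"), c(n_pos, n_neg)),
                      stringsAsFactors = FALSE)
  structure(list(pairs = pairs, n_positive = n_pos, n_negative = n_neg),
            class = "pair_set")
}

#' Write a dataset as a directory tree with a manifest
#'
#' Layout: `<split>/<identity>/<index>.png` plus `manifest.json` (identities,
#' per-image provenance, seed); pair sets are written as CSV with columns
#' `path_a`, `path_b`, `label`.
#'
#' @param split a `dataset_split`.
#' @param dir output directory (created; must not exist unless `force`).
#' @param pairs optional `pair_set` over the test images.
#' @param force overwrite an existing directory.
#' @return invisibly, the manifest as a list.
#' @export
write_dataset <- function(split, dir, pairs = NULL, force = FALSE) {
  stopifnot(inherits(split, "dataset_split"))
  if (dir.exists(dir) && !force) stop("output directory exists (use force = TRUE)")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(seed = split$seed, identity_partition = as.list(split$identity_partition),
                   images = list())
  paths <- list()
  for (part in c("train", "val", "test")) {
    imgs <- split[[part]]
    cnt <- list()
    paths[[part]] <- character(length(imgs))
    for (i in seq_along(imgs)) {
      im <- imgs[[i]]
      id <- as.character(im$identity)
      cnt[[id]] <- (cnt[[id]] %||% 0L) + 1L
      d <- file.path(dir, part, id)
      dir.create(d, recursive = TRUE, showWarnings = FALSE)
      p <- file.path(d, sprintf("%03d.png", cnt[[id]]))
      png::writePNG(im$pixels, p)
      paths[[part]][i] <- p
      manifest$images[[length(manifest$images) + 1L]] <-
        c(list(path = p, split = part, identity = im$identity), im$provenance)
    }
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  if (!is.null(pairs)) {
    pp <- pairs$pairs
    utils::write.csv(data.frame(path_a = paths$test[pp$a],
                                path_b = paths$test[pp$b],
                                label = pp$label),
                     file.path(dir, "pairs.csv"), row.names = FALSE)
  }
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
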