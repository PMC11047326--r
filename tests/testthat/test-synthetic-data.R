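# Synthetic coat-pattern generator: determinism, rendering geometry,
# open-set splits, pair construction, SSIM deduplication.

test_that("identity templates are deterministic and distinct across identities", {
  a1 <- generate_identity(0L, 42L)
  a2 <- generate_identity(0L, 42L)
  expect_identical(a1, a2)
  b <- generate_identity(1L, 42L)
  expect_false(identical(a1$blob_set, b$blob_set))
  # degenerate config: zero blobs -> explicit low-feature template
  lf <- generate_identity(0L, 42L,
                          pattern_config(blob_count_range = c(0L, 0L)))
  expect_true(lf$low_feature)
  expect_equal(nrow(lf$blob_set), 0L)
  expect_error(pattern_config(blob_count_range = c(3L, 1L)),
               "blob-count range")
})

test_that("blob centers lie inside the canonical body outline", {
  for (id in 0:5) {
    tpl <- generate_identity(id, 7L)
    q <- ((tpl$blob_set$cx - 0.5) / 0.5)^2 +
      ((tpl$blob_set$cy - 0.5) / (0.5 / tpl$body_aspect))^2
    expect_true(all(q <= 1))
  }
})

test_that("rendered body bounding box matches the template aspect ratio", {
  tpl <- generate_identity(2L, 5L)
  im <- render_instance(tpl, render_spec(orientation_deg = 0,
                                         canvas = c(160L, 224L),
                                         noise_sd = 0))
  # body pixels are brighter than the mid-gray background
  mask <- im$pixels > 0.6
  rows <- range(which(rowSums(mask) > 0))
  cols <- range(which(colSums(mask) > 0))
  box_aspect <- diff(cols) / diff(rows)
  expect_equal(box_aspect, tpl$body_aspect, tolerance = 0.05)
  expect_equal(im$identity, 2L)
  expect_equal(im$provenance$lighting, "natural")
})

test_that("a 180-degree render equals the 0-degree render rotated 180 degrees", {
  tpl <- generate_identity(3L, 9L)
  sp0 <- render_spec(orientation_deg = 0, noise_sd = 0)
  sp180 <- render_spec(orientation_deg = 180, noise_sd = 0)
  im0 <- render_instance(tpl, sp0)$pixels
  im180 <- render_instance(tpl, sp180)$pixels
  rot180 <- im0[nrow(im0):1L, ncol(im0):1L]
  expect_lt(max(abs(im180 - rot180)), 0.02)
})

test_that("artificial lighting darkens the image", {
  tpl <- generate_identity(1L, 3L)
  nat <- render_instance(tpl, render_spec(orientation_deg = 45,
                                          lighting = "natural",
                                          noise_sd = 0))
  art <- render_instance(tpl, render_spec(orientation_deg = 45,
                                          lighting = "artificial",
                                          shadow_strength = 0.5,
                                          noise_sd = 0))
  expect_lt(mean(art$pixels), mean(nat$pixels))
  # lighting invariants are enforced at construction
  expect_error(render_spec(lighting = "natural", shadow_strength = 0.3),
               "natural")
  expect_error(render_spec(lighting = "artificial", shadow_strength = 0),
               "artificial")
})

test_that("occlusion is painted inside the canvas and validated", {
  tpl <- generate_identity(0L, 1L)
  im <- render_instance(tpl, render_spec(occlusion_rect = c(10, 20, 15, 12),
                                         noise_sd = 0))
  expect_true(all(im$pixels[20:31, 10:24] == 0))
  expect_true(im$provenance$occluded)
  expect_error(render_instance(tpl,
                               render_spec(occlusion_rect = c(150, 20, 15, 12))),
               "occlusion_rect")
})

test_that("dataset split counts follow the 8:2 rule and identities are disjoint", {
  split <- generate_dataset(5L, 2L, 10L, seed = 1L, canvas = tiny_canvas)
  expect_length(split$train, 5L * 8L)
  expect_length(split$val, 5L * 2L)
  expect_length(split$test, 2L * 10L)
  ids <- function(part) unique(vapply(part, `[[`, integer(1), "identity"))
  expect_length(intersect(c(ids(split$train), ids(split$val)),
                          ids(split$test)), 0L)
  # identical seed, identical split
  split2 <- generate_dataset(5L, 2L, 10L, seed = 1L, canvas = tiny_canvas)
  expect_identical(split, split2)
  expect_error(generate_dataset(5L, 0L, 10L), "open-set")
})

test_that("the open-set property holds across many seeds", {
  for (seed in seq_len(100L)) {
    split <- generate_dataset(2L, 1L, 2L, seed = seed, canvas = c(32L, 32L),
                              noise_sd = 0)
    ids <- function(part) unique(vapply(part, `[[`, integer(1), "identity"))
    expect_length(intersect(c(ids(split$train), ids(split$val)),
                            ids(split$test)), 0L)
  }
})

test_that("pair sets are balanced, label-correct and seeded", {
  split <- tiny_split()
  ps <- make_pairs(split$test, 15L, 15L, seed = 7L)
  expect_equal(ps$n_positive, 15L)
  expect_equal(ps$n_negative, 15L)
  expect_equal(nrow(ps$pairs), 30L)
  labels <- vapply(split$test, `[[`, integer(1), "identity")
  # exhaustive label check and no self-pairs
  for (i in seq_len(nrow(ps$pairs))) {
    a <- ps$pairs$a[i]; b <- ps$pairs$b[i]
    expect_false(a == b)
    if (ps$pairs$label[i] == "same") {
      expect_equal(labels[a], labels[b])
    } else {
      expect_false(labels[a] == labels[b])
    }
  }
  expect_identical(ps, make_pairs(split$test, 15L, 15L, seed = 7L))
  # no repeated unordered pair
  key <- paste(pmin(ps$pairs$a, ps$pairs$b), pmax(ps$pairs$a, ps$pairs$b),
               ps$pairs$label)
  expect_equal(anyDuplicated(key), 0L)
})

test_that("pair construction degenerate and error cases", {
  ps <- pairs_from_labels(c(1L, 1L, 2L, 2L), 1L, 1L, seed = 1L)
  expect_equal(nrow(ps$pairs), 2L)
  expect_setequal(ps$pairs$label, c("same", "different"))
  expect_error(pairs_from_labels(c(1L, 2L), 1L, 1L), ">= 2 images")
  expect_error(pairs_from_labels(c(1L, 1L, 2L, 2L), 1L, 2L), "balanced")
  # more positives requested than distinct same-identity pairs exist
  expect_error(pairs_from_labels(c(1L, 1L, 2L, 2L), 5L, 5L), "positive pairs")
})

test_that("the dataset writer produces the documented layout", {
  dir <- withr::local_tempdir()
  split <- tiny_split()
  ps <- make_pairs(split$test, 5L, 5L, seed = 3L)
  write_dataset(split, file.path(dir, "ds"), pairs = ps, force = FALSE)
  expect_true(file.exists(file.path(dir, "ds", "manifest.json")))
  expect_true(file.exists(file.path(dir, "ds", "pairs.csv")))
  expect_true(dir.exists(file.path(dir, "ds", "train", "0")))
  pairs_csv <- read.csv(file.path(dir, "ds", "pairs.csv"))
  expect_named(pairs_csv, c("path_a", "path_b", "label"))
  expect_true(all(file.exists(pairs_csv$path_a)))
  # a written PNG round-trips
  px <- png::readPNG(pairs_csv$path_a[1])
  expect_equal(dim(px), as.integer(tiny_canvas))
  expect_error(write_dataset(split, file.path(dir, "ds")), "exists")
})
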