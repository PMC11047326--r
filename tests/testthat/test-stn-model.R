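# Spatial transformer components, attention modules, and the embedding
# network.

test_that("grid_generator reproduces the normalized lattice and affine shifts", {
  idg <- grid_generator(matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE),
                        c(4, 5))
  expect_equal(idg[, , 1], matrix(seq(-1, 1, length.out = 5), 4, 5,
                                  byrow = TRUE))
  expect_equal(idg[, , 2], matrix(seq(-1, 1, length.out = 4), 4, 5))
  shifted <- grid_generator(matrix(c(1, 0, 0.5, 0, 1, 0), 2, 3, byrow = TRUE),
                            c(4, 5))
  expect_equal(shifted[, , 1], idg[, , 1] + 0.5)
  expect_equal(shifted[, , 2], idg[, , 2])
})

test_that("grid_generator matches a per-pixel matrix-multiply oracle", {
  set.seed(3)
  theta <- matrix(rnorm(6), 2, 3)
  g <- grid_generator(theta, c(4, 4))
  xt <- seq(-1, 1, length.out = 4)
  yt <- seq(-1, 1, length.out = 4)
  for (i in 1:4) for (j in 1:4) {
    src <- theta %*% c(xt[j], yt[i], 1)
    expect_equal(g[i, j, ], as.vector(src), tolerance = 1e-6)
  }
})

test_that("bilinear sampling: identity, constants, and the 2x2 center", {
  f <- rand_fmap(3, 6, 7, seed = 5)
  idg <- grid_generator(matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE),
                        c(6, 7))
  expect_equal(bilinear_sample(f, idg), f, tolerance = 1e-6)
  const <- array(2.5, c(1, 4, 4))
  g_in <- grid_generator(matrix(c(0.5, 0, 0.1, 0, 0.5, -0.1), 2, 3,
                                byrow = TRUE), c(4, 4))
  expect_equal(bilinear_sample(const, g_in), array(2.5, c(1, 4, 4)),
               tolerance = 1e-12)
  # single sample at the exact center of a 2x2 block: the 4-pixel mean
  block <- array(c(1, 3, 2, 4), c(1, 2, 2))  # [[1,2],[3,4]] row-major
  center <- array(0, c(1, 1, 2))             # (0,0) in normalized coords
  expect_equal(as.numeric(bilinear_sample(block, center)), 2.5)
})

test_that("untrained localization is the identity transform", {
  stn <- new_stn(4, hidden = 16)
  f <- rand_fmap(4, 5, 5, seed = 9)
  th <- localization(stn, f)
  expect_equal(dim(th), c(2L, 3L))
  expect_equal(th, matrix(c(1, 0, 0, 0, 1, 0), 2, 3, byrow = TRUE))
  expect_equal(stn_transform(stn, f), f, tolerance = 1e-6)
  expect_error(localization(stn, f * NA), "non-finite")
})

test_that("trained localization responds to its input and passes gradient", {
  stn <- new_stn(2, hidden = 8)
  f <- rand_fmap(2, 6, 6, seed = 1)
  # one gradient step on a loss that wants a shifted output
  xb <- array(f, c(dim(f), 1))
  fw <- cowreid:::stn_layer_fwd(stn, xb)
  dy <- array(1, dim(fw$y))
  bw <- cowreid:::stn_layer_bwd(stn, dy, fw$cache)
  # gradient w.r.t. localization parameters is nonzero for non-constant input
  expect_gt(max(abs(bw$grads$W2)), 0)
  stn$par$W2 <- stn$par$W2 - 0.1 * bw$grads$W2
  stn$par$b2 <- stn$par$b2 - 0.1 * bw$grads$b2
  th1 <- localization(stn, f)
  th2 <- localization(stn, rand_fmap(2, 6, 6, seed = 2))
  expect_false(isTRUE(all.equal(th1, matrix(c(1, 0, 0, 0, 1, 0), 2, 3,
                                            byrow = TRUE))))
  expect_false(isTRUE(all.equal(th1, th2)))
})

test_that("attention modules preserve shape and gate as designed", {
  f <- rand_fmap(8, 5, 6, seed = 21)
  for (kind in c("cbam", "simam", "parnet")) {
    att <- new_attention(kind, 8)
    out <- apply_attention(att, f)
    expect_equal(dim(out), dim(f))
  }
  # CBAM: product of sigmoid gates can only shrink magnitudes
  cb <- new_attention("cbam", 8)
  out <- apply_attention(cb, f)
  expect_true(all(abs(out) <= abs(f) + 1e-12))
  expect_equal(apply_attention(cb, f * 0), f * 0)
  # ParNet SSE: zero in, zero out; gates strictly inside (0,1)
  pn <- new_attention("parnet", 8)
  expect_equal(apply_attention(pn, f * 0), f * 0)
  g <- cowreid:::sigmoid(pn$par$W %*% rowMeans(matrix(f, 8)) + pn$par$b)
  expect_true(all(g > 0 & g < 1))
})

test_that("SimAM adds no parameters and gates uniformly on constant channels", {
  att <- new_attention("simam", 16)
  expect_equal(n_parameters(att), 0)
  f <- rand_fmap(2, 4, 4, seed = 2)
  f[2, , ] <- 3.14                       # spatially constant channel
  out <- attention_simam(f)
  gate <- out[2, , ] / f[2, , ]
  expect_equal(max(gate) - min(gate), 0, tolerance = 1e-12)
  expect_error(attention_simam(array(1, c(3, 1, 1))), "spatial")
})

test_that("models with and without the STN are identical until trained", {
  cfg_stn <- backbone_config("tiny", attention = "simam", input_size = 16L)
  cfg_no <- backbone_config("tiny", attention = "simam", input_size = 16L,
                            use_stn = FALSE)
  m1 <- new_model(cfg_stn, n_classes = 3L, seed = 4L)
  m2 <- new_model(cfg_no, n_classes = 3L, seed = 4L)
  set.seed(31)
  imgs <- lapply(1:3, function(i) matrix(runif(256), 16, 16))
  expect_equal(embed(m1, imgs), embed(m2, imgs), tolerance = 1e-9)
})

test_that("embed returns one deterministic row per image", {
  cfg <- backbone_config("tiny", attention = "none", input_size = 16L)
  m <- new_model(cfg, n_classes = 0L, seed = 1L)
  set.seed(8)
  imgs <- lapply(1:4, function(i) matrix(runif(256), 16, 16))
  e1 <- embed(m, imgs)
  expect_equal(dim(e1), c(4L, cfg$embedding_dim))
  expect_identical(e1, embed(m, imgs))
  expect_true(all(is.finite(e1)))
  expect_error(embed(m, list(matrix(0, 8, 8))), "input size")
})

test_that("forward and backward on a small batch complete quickly", {
  cfg <- backbone_config("tiny", attention = "simam", input_size = 32L)
  m <- new_model(cfg, n_classes = 4L, seed = 2L)
  x <- array(runif(1 * 32 * 32 * 4), c(1, 32, 32, 4))
  elapsed <- system.time({
    fw <- cowreid:::model_forward(m, x, training = TRUE)
    lr <- arcface_loss(t(fw$emb), c(1, 2, 3, 4), m$head)
    cowreid:::model_backward(m, fw, t(lr$d_embeddings))
  })[3]
  expect_lt(elapsed, 10)
})

test_that("classification scores agree with a brute-force oracle", {
  set.seed(6)
  head <- matrix(rnorm(5 * 8), 5, 8)
  emb <- matrix(rnorm(3 * 8), 3, 8)
  sc <- classify(emb, head, mode = "cosine")
  for (i in 1:3) for (j in 1:5) {
    expect_equal(sc[i, j],
                 sum(emb[i, ] * head[j, ]) /
                   (sqrt(sum(emb[i, ]^2)) * sqrt(sum(head[j, ]^2))),
                 tolerance = 1e-6)
  }
  sd <- classify(emb, head, mode = "dot")
  expect_equal(sd, emb %*% t(head), tolerance = 1e-6)
  # an embedding equal to a normalized head row scores cosine 1 on that class
  e <- head[2, ] / sqrt(sum(head[2, ]^2))
  expect_equal(classify(e, head, "cosine")[1, 2], 1, tolerance = 1e-9)
  orth <- c(head[1, 2], -head[1, 1], rep(0, 6))
  expect_equal(classify(orth, head, "cosine")[1, 1], 0, tolerance = 1e-9)
})

test_that("checkpoints round-trip through a single file", {
  cfg <- backbone_config("tiny", input_size = 16L)
  m <- new_model(cfg, n_classes = 2L, seed = 3L)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path, extra = list(note = "fit"))
  back <- load_checkpoint(path)
  expect_equal(back$model, m)
  expect_equal(back$extra$note, "fit")
})
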