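# Shared fixtures, built in code at test time.

# Small canvas keeps rendering fast; 32x32 is the renderer's minimum.
tiny_canvas <- c(48L, 36L)

# Memoized small rendered dataset shared by tests that only read it.
.fixture_env <- new.env(parent = emptyenv())

tiny_split <- function() {
  if (is.null(.fixture_env$split)) {
    .fixture_env$split <- generate_dataset(3L, 2L, 6L, seed = 11L,
                                           canvas = tiny_canvas)
  }
  .fixture_env$split
}

# Deterministic random feature map (C,H,W) for attention/STN tests.
rand_fmap <- function(C = 3L, H = 6L, W = 7L, seed = 1L) {
  set.seed(seed)
  array(rnorm(C * H * W), c(C, H, W))
}

# Separable embeddings: identities occupy distinct orthants with small noise.
separable_embeddings <- function(n_ids = 4L, per_id = 10L, dim = 8L,
                                 noise = 0.05, seed = 1L) {
  set.seed(seed)
  centers <- matrix(rnorm(n_ids * dim, sd = 2), n_ids, dim)
  emb <- centers[rep(seq_len(n_ids), each = per_id), ] +
    matrix(rnorm(n_ids * per_id * dim, sd = noise), n_ids * per_id, dim)
  list(embeddings = emb, labels = rep(seq_len(n_ids), each = per_id))
}

# Balanced pair set over labelled items (for openset tests without images).
pairs_from_labels <- function(labels, n_pos, n_neg, seed = 1L) {
  imgs <- lapply(labels, function(l)
    structure(list(pixels = matrix(0, 2, 2), identity = l,
                   provenance = list()), class = "labeled_image"))
  make_pairs(imgs, n_pos, n_neg, seed = seed)
}
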