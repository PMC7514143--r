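test_that("left/right context dimensions are twice the hidden size", {
  cfg <- network_config(n_w = 5, hidden = 3, n_fused = 6, n_d = 2,
                        filter_sizes = 2L, dilated_sizes = 2L,
                        n_filters = 3L, max_len = 8L, dropout = 0)
  model <- init_ddi_model(cfg, tiny_vocab(), seed = 1)
  x <- matrix(rnorm(4 * 5), 4, 5)
  ctx <- context_encode(x, model)
  expect_equal(dim(ctx$left), c(4, 6))
  expect_equal(dim(ctx$right), c(4, 6))
  expect_error(context_encode(matrix(0, 0, 5), model), "empty")
})

test_that("the left context is causal and the right context anticausal", {
  set.seed(31)
  cfg <- tiny_config()
  model <- init_ddi_model(cfg, tiny_vocab(), seed = 2)
  x <- matrix(rnorm(6 * cfg$n_w), 6, cfg$n_w)
  base <- context_encode(x, model)
  # permuting tokens after position i leaves left_context(i) unchanged
  xp <- x; xp[5:6, ] <- x[6:5, ]
  perm <- context_encode(xp, model)
  expect_equal(perm$left[1:4, ], base$left[1:4, ])
  # permuting tokens before position i leaves right_context(i) unchanged
  xq <- x; xq[1:2, ] <- x[2:1, ]
  permq <- context_encode(xq, model)
  expect_equal(permq$right[3:6, ], base$right[3:6, ])
  # a length-1 sequence has no neighbours: both contexts equal the boundary
  # state (zero, at zero gate bias)
  one <- context_encode(x[1, , drop = FALSE], model)
  expect_equal(as.vector(one$left), numeric(6))
  expect_equal(as.vector(one$right), numeric(6))
})

test_that("semantic fusion is the stated affine map on the 600-style concatenation", {
  cfg <- network_config(n_w = 5, hidden = 3, n_fused = 4, n_d = 2,
                        filter_sizes = 2L, dilated_sizes = 2L,
                        n_filters = 3L, max_len = 8L, dropout = 0)
  d <- ddinet:::config_dims(cfg)
  expect_equal(d$n_s, 2 * 2 * cfg$hidden + cfg$n_w)
  model <- init_ddi_model(cfg, tiny_vocab(), seed = 3)
  word <- rnorm(cfg$n_w); left <- rnorm(d$n_l); right <- rnorm(d$n_r)
  # zero weights and bias give zero output
  m0 <- model; m0$params$Ws[] <- 0; m0$params$bs[] <- 0
  expect_equal(fuse_semantic(word, left, right, m0), numeric(cfg$n_fused))
  # an identity block reproduces the selected input slice
  mi <- model; mi$params$Ws[] <- 0; mi$params$bs[] <- 0
  mi$params$Ws[(d$n_l + 1):(d$n_l + cfg$n_fused), ] <- diag(cfg$n_fused)
  expect_equal(fuse_semantic(word, left, right, mi), word[1:cfg$n_fused])
  expect_error(fuse_semantic(word[-1], left, right, model), "dimensions")
})

test_that("instance embedding concatenates semantic and position parts", {
  cfg <- tiny_config()
  model <- init_ddi_model(cfg, tiny_vocab(), seed = 4)
  set.seed(5)
  e1 <- random_encoded(cfg, model$vocab)
  E <- embed_instance(e1, model)
  expect_equal(dim(E), c(cfg$max_len, cfg$n_fused + 2 * cfg$n_d))
  # same tokens, different entity positions: semantic part equal, position part not
  e2 <- e1
  e2$dist1 <- rev(e1$dist1)
  E2 <- embed_instance(e2, model)
  expect_equal(E2[, 1:cfg$n_fused], E[, 1:cfg$n_fused])
  expect_false(isTRUE(all.equal(E2[, cfg$n_fused + 1:cfg$n_d],
                                E[, cfg$n_fused + 1:cfg$n_d])))
  # padding positions (id 0) use the index-0 embedding rows
  pad <- e1; pad$token_ids[] <- 0L; pad$dist1[] <- 0L; pad$dist2[] <- 0L
  Epad <- embed_instance(pad, model)
  expect_true(all(Epad[, cfg$n_fused + 1:(2 * cfg$n_d)] == 0))
  bad <- e1; bad$dist1[1] <- 10000L
  expect_error(embed_instance(bad, model), "outside")
})

test_that("convolution output lengths match a brute-force window enumerator", {
  brute_len <- function(n, k, d) {
    sum(vapply(seq_len(n), function(i) i + (k - 1) * d <= n, logical(1)))
  }
  set.seed(8)
  for (n in c(5, 9, 16)) {
    for (k in 2:4) {
      for (d in 1:3) {
        if (brute_len(n, k, d) < 1) next
        E <- matrix(rnorm(n * 3), n, 3)
        W <- matrix(rnorm(k * 3 * 2), k * 3, 2)
        out <- dilated_conv(E, W, b = c(0, 0), d = d)
        expect_equal(nrow(out), brute_len(n, k, d))
        if (d == 1) expect_equal(nrow(out), n - k + 1)
      }
    }
  }
  E <- matrix(rnorm(4 * 3), 4, 3)
  W <- matrix(rnorm(5 * 3 * 2), 15, 2)
  expect_error(typical_conv(E, W, c(0, 0)), "too short")
  expect_error(dilated_conv(matrix(rnorm(12), 4, 3),
                            matrix(rnorm(3 * 3 * 2), 9, 2), c(0, 0), d = 2),
               "too short")
})

test_that("a dilated convolution with d = 1 equals the typical convolution", {
  set.seed(13)
  for (trial in 1:100) {
    n <- sample(4:12, 1); c_in <- sample(2:4, 1); k <- sample(2:3, 1)
    E <- matrix(rnorm(n * c_in), n, c_in)
    W <- matrix(rnorm(k * c_in * 3), k * c_in, 3)
    b <- rnorm(3)
    expect_equal(dilated_conv(E, W, b, d = 1), typical_conv(E, W, b))
  }
})

test_that("convolution honours its closed-form cases", {
  # k=1 coordinate-selector filter reproduces the positive part of a channel
  E <- matrix(c(-1, 2, 0.5, -3, 4, 1), 3, 2)
  W <- matrix(c(1, 0), 2, 1)  # selects channel 1
  expect_equal(as.vector(typical_conv(E, W, 0)), pmax(E[, 1], 0))
  # all-zero input with zero bias gives all-zero output
  expect_equal(typical_conv(matrix(0, 5, 2), matrix(rnorm(4), 4, 1), 0),
               matrix(0, 4, 1))
  # dilated taps skip d-1 positions: receptive span (k-1)*d + 1
  Eimp <- matrix(0, 7, 1); Eimp[c(1, 3, 5), 1] <- c(1, 10, 100)
  Wd <- matrix(c(1, 1, 1), 3, 1)
  out <- dilated_conv(Eimp, Wd, 0, d = 2)
  expect_equal(out[1, 1], 111)  # taps at offsets 0, 2, 4
})

test_that("max pooling matches a brute-force sliding maximum", {
  expect_equal(as.vector(max_pool(matrix(c(1, 3, 2, 5)), 2)), c(3, 5))
  expect_equal(as.vector(max_pool(matrix(rep(7, 6)), 3)), c(7, 7))
  expect_equal(as.vector(max_pool(matrix(c(4, -1, 2, 9, 0)), 5)), 9)
  expect_error(max_pool(matrix(1), 2), "shorter than")
  set.seed(17)
  for (trial in 1:25) {
    L <- sample(3:12, 1); w <- sample(2:4, 1); nf <- sample(1:3, 1)
    if (L < w) next
    F <- matrix(rnorm(L * nf), L, nf)
    got <- max_pool(F, w)
    starts <- seq(1, L, by = w)
    want <- t(vapply(starts, function(s)
      apply(F[s:min(s + w - 1, L), , drop = FALSE], 2, max), numeric(nf)))
    expect_equal(got, matrix(want, length(starts), nf))
  }
})

test_that("the forward pass yields a proper probability distribution over 5 classes", {
  cfg <- tiny_config()
  model <- init_ddi_model(cfg, tiny_vocab(), seed = 21)
  set.seed(22)
  for (trial in 1:20) {
    p <- ddi_forward(model, random_encoded(cfg, model$vocab))
    expect_length(p, 5)
    expect_named(p, ddi_classes())
    expect_equal(sum(p), 1)
    expect_true(all(p > 0 & p < 1))
  }
})

test_that("the forward pass is deterministic with dropout disabled and stochastic in training", {
  cfg <- tiny_config()
  model <- init_ddi_model(cfg, tiny_vocab(), seed = 23)
  set.seed(24)
  enc <- random_encoded(cfg, model$vocab)
  expect_identical(ddi_forward(model, enc), ddi_forward(model, enc))
  cfg_do <- tiny_config(); cfg_do$dropout <- 0.5
  model_do <- model; model_do$config <- cfg_do
  set.seed(25)
  a <- ddi_forward(model_do, enc, train = TRUE)
  b <- ddi_forward(model_do, enc, train = TRUE)
  expect_false(identical(a, b))
})

test_that("pretrained embeddings are adopted and OOV tokens keep their seeded draw", {
  v <- build_vocab(list(c("alpha", "beta", "gamma")))
  emb <- matrix(seq_len(2 * 5) / 10, 2, 5,
                dimnames = list(c("alpha", "unrelated"), NULL))
  cfg <- tiny_config()
  m <- init_ddi_model(cfg, v, embeddings = emb, seed = 31)
  m0 <- init_ddi_model(cfg, v, seed = 31)
  expect_equal(m$params$Ew[v$ids[["alpha"]] + 1L, ], emb["alpha", ])
  expect_equal(m$params$Ew[v$ids[["beta"]] + 1L, ],
               m0$params$Ew[v$ids[["beta"]] + 1L, ])
  f <- withr::local_tempfile(fileext = ".txt")
  write_word2vec(emb, f)
  emb2 <- read_word2vec(f)
  expect_equal(emb2, emb)
  expect_error(read_word2vec(withr::local_tempfile(lines = "not a header")),
               "header")
})

test_that("model checkpoints round-trip through disk", {
  cfg <- tiny_config()
  model <- init_ddi_model(cfg, tiny_vocab(), seed = 41)
  f <- withr::local_tempfile(fileext = ".rds")
  save_ddi_model(model, f)
  m2 <- load_ddi_model(f)
  expect_equal(m2$params, model$params)
  set.seed(42)
  enc <- random_encoded(cfg, model$vocab)
  expect_identical(ddi_forward(m2, enc), ddi_forward(model, enc))
})
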