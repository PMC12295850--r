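test_that("configuration invariants are enforced", {
  expect_error(kn_config(num_classes = 3, group_count = 7),
               "stage 1.*96.*not divisible by group_count")
  expect_error(kn_config(num_classes = 1), "num_classes")
  expect_error(kn_config(num_classes = 3, input_size = 100), "divisible")
  # 48/4 = 12 halves to 6 then 3: third transition would see an odd size
  expect_error(kn_config(num_classes = 3, input_size = 48), "odd")
  expect_silent(validate_config(tiny_cfg()))
})

test_that("shape trace reproduces the reference stage table", {
  tr <- shape_trace(kn_config(num_classes = 3))
  expect_equal(tr$height, c(56L, 28L, 14L, 7L, 1L, 1L))
  expect_equal(tr$width, c(56L, 28L, 14L, 7L, 1L, 1L))
  expect_equal(tr$channels, c(96L, 192L, 384L, 768L, 768L, 3L))
  # spatial halving and channel doubling across stages 1-3
  expect_equal(tr$height[2:4], tr$height[1:3] / 2L)
  expect_equal(tr$channels[2:4], tr$channels[1:3] * 2L)

  tr448 <- shape_trace(kn_config(num_classes = 3, input_size = 448))
  expect_equal(tr448$height[1], 112L)
  expect_equal(tr448$height[4], 14L)

  trt <- shape_trace(tiny_cfg(num_classes = 5, input_size = 64,
                              stage_channels = c(8, 16, 32, 64)))
  expect_equal(trt$channels[5], 64L)   # final pooled dimension
  expect_equal(trt$channels[6], 5L)
})

test_that("parameter count equals the closed-form arithmetic oracle", {
  m <- build_model(kn_config(num_classes = 3), seed = 1)
  n_ref <- oracle_param_count(c(96, 192, 384, 768), 6, 3)
  expect_identical(count_parameters(m), as.integer(n_ref))
  expect_equal(round(count_parameters(m) / 1e6, 1), 7.1)

  mt <- tiny_model()
  expect_identical(count_parameters(mt),
                   as.integer(oracle_param_count(c(4, 8, 16, 32), 2, 3)))

  # one extra class adds exactly D + 1 parameters
  m4 <- build_model(kn_config(num_classes = 4), seed = 1)
  expect_identical(count_parameters(m4) - count_parameters(m), 768L + 1L)

  # resolution does not change the parameter count
  m448 <- build_model(kn_config(num_classes = 3, input_size = 448), seed = 1)
  expect_identical(count_parameters(m448), count_parameters(m))
})

test_that("model building is seed-deterministic", {
  a <- tiny_model(seed = 7)
  b <- tiny_model(seed = 7)
  c <- tiny_model(seed = 8)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$stem.conv1.w, c$params$stem.conv1.w))
})

test_that("grouped convolution matches the direct-summation oracle", {
  set.seed(21)
  for (g in c(1L, 2L)) {
    x <- array(rnorm(6 * 6 * 4), c(6, 6, 4))
    w <- array(rnorm(3 * 3 * (4 %/% g) * 6), c(3, 3, 4 %/% g, 6))
    b <- rnorm(6)
    expect_equal(conv2d(x, w, b, stride = 1, pad = 1, groups = g),
                 oracle_conv2d(x, w, b, stride = 1, pad = 1, groups = g),
                 tolerance = 1e-10)
  }
  # strided, unpadded
  x <- array(rnorm(8 * 8 * 3), c(8, 8, 3))
  w <- array(rnorm(4 * 4 * 3 * 5), c(4, 4, 3, 5))
  expect_equal(conv2d(x, w, NULL, stride = 4),
               oracle_conv2d(x, w, NULL, stride = 4), tolerance = 1e-10)
  expect_error(conv2d(x, array(0, c(3, 3, 2, 6)), NULL), "channel mismatch")
})

test_that("stem averages two conv-BN-GELU branches and matches its oracle", {
  m <- tiny_model(seed = 3)
  set.seed(4)
  x <- array(runif(8 * 8 * 3), c(8, 8, 3))
  got <- stem_forward(m, x)
  expect_equal(dim(got), c(2L, 2L, 4L))
  ref1 <- init_bn_gelu(oracle_conv2d(x, m$params$stem.conv1.w,
                                     m$params$stem.conv1.b, stride = 4))
  ref2 <- init_bn_gelu(oracle_conv2d(x, m$params$stem.conv2.w,
                                     m$params$stem.conv2.b, stride = 4))
  expect_equal(got, (ref1 + ref2) / 2, tolerance = 1e-5)

  # identical branch parameters collapse the average to a single branch
  m2 <- m
  m2$params$stem.conv2.w <- m2$params$stem.conv1.w
  m2$params$stem.conv2.b <- m2$params$stem.conv1.b
  expect_equal(stem_forward(m2, x), ref1, tolerance = 1e-5)

  expect_error(stem_forward(m, array(0, c(7, 7, 3))), "shape error")
})

test_that("pooling branches match exhaustive sliding-window oracles", {
  set.seed(5)
  x <- array(rnorm(5 * 5 * 6), c(5, 5, 6))
  expect_equal(max_pool2d(x), oracle_pool(x, "max"), tolerance = 1e-12)
  expect_equal(avg_pool2d(x), oracle_pool(x, "avg"), tolerance = 1e-12)
  # a spatially constant map is reproduced exactly, including borders
  const <- array(rep(seq_len(6), each = 25) * 0.1, c(5, 5, 6))
  expect_equal(max_pool2d(const), const)
  expect_equal(avg_pool2d(const), const)
})

test_that("blocks preserve shape and reduce to identity with zeroed compression", {
  m <- tiny_model(seed = 9)
  set.seed(10)
  x <- array(runif(8 * 8 * 4), c(8, 8, 4))
  y <- block_forward(m, x, stage = 1)
  expect_equal(dim(y), dim(x))
  expect_true(all(is.finite(y)))
  expect_error(block_forward(m, array(0, c(8, 8, 6)), stage = 1), "shape error")

  # zero compression conv => the residual shortcut is an exact identity
  m0 <- m
  m0$params$`s1.b1.cmp.w`[] <- 0
  m0$params$`s1.b1.cmp.b`[] <- 0
  expect_equal(block_forward(m0, x, stage = 1), x, tolerance = 1e-12)
  # without the shortcut the same block collapses to GELU(0) = 0
  mnores <- build_model(tiny_cfg(use_residual = FALSE), seed = 9)
  mnores$params$`s1.b1.cmp.w`[] <- 0
  mnores$params$`s1.b1.cmp.b`[] <- 0
  expect_equal(max(abs(block_forward(mnores, x, stage = 1))), 0)
})

test_that("transitions halve spatial size, double channels, reject odd input", {
  m <- tiny_model(seed = 2)
  x <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  expect_equal(dim(transition_forward(m, x, which = 1)), c(4L, 4L, 8L))
  x2 <- array(rnorm(4 * 4 * 8), c(4, 4, 8))
  expect_equal(dim(transition_forward(m, x2, which = 2)), c(2L, 2L, 16L))
  expect_error(transition_forward(m, array(0, c(7, 7, 4)), which = 1),
               "shape error")
})

test_that("head pools globally and returns a probability distribution", {
  m <- tiny_model(seed = 6)
  set.seed(11); m$params$head.w[] <- rnorm(length(m$params$head.w), sd = 0.3)
  x <- array(rnorm(2 * 2 * 32), c(2, 2, 32))
  out <- head_forward(m, x)
  expect_length(out$pooled, 32L)
  expect_true(all(out$probs >= 0))
  expect_equal(sum(out$probs), 1, tolerance = 1e-6)
  # spatially constant map pools to its per-channel value
  v <- seq_len(32) / 10
  xc <- array(rep(v, each = 4), c(2, 2, 32))
  expect_equal(head_forward(m, xc)$pooled, v)
  expect_error(head_forward(m, array(0, c(2, 2, 16))), "shape error")
})

test_that("the full forward pass is deterministic, finite, and normalized", {
  m <- tiny_model(seed = 12)
  set.seed(13); m$params$head.w[] <- rnorm(length(m$params$head.w), sd = 0.2)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  one <- model_forward(m, img)
  expect_equal(dim(one$probs), c(1L, 3L))
  expect_equal(sum(one$probs), 1, tolerance = 1e-6)
  batch <- array(0, c(32, 32, 3, 2))
  batch[, , , 1] <- img; batch[, , , 2] <- img
  two <- model_forward(m, batch)
  expect_equal(two$probs[1, ], two$probs[2, ])
  zero <- model_forward(m, array(0, c(32, 32, 3)))
  expect_true(all(is.finite(zero$logits)))
  expect_error(model_forward(m, array(0, c(16, 16, 3))), "shape error")
})

test_that("forward-pass intermediate shapes equal the symbolic trace", {
  cfg <- tiny_cfg(input_size = 64, stage_channels = c(8, 16, 32, 64))
  m <- build_model(cfg, seed = 1)
  tr <- shape_trace(cfg)
  x <- array(runif(64 * 64 * 3), c(64, 64, 3, 1))
  h <- stem_forward(m, x)
  expect_equal(dim(h)[1:3], c(tr$height[1], tr$width[1], tr$channels[1]))
  for (s in 1:3) {
    h <- block_forward(m, h, stage = s)
    h <- transition_forward(m, h, which = s)
    expect_equal(dim(h)[1:3],
                 c(tr$height[s + 1], tr$width[s + 1], tr$channels[s + 1]))
  }
  h <- block_forward(m, h, stage = 4)
  expect_equal(dim(h)[3], tr$channels[5])
})

test_that("checkpoints round-trip to identical forward outputs", {
  m <- tiny_model(seed = 20)
  set.seed(21); m$params$head.w[] <- rnorm(length(m$params$head.w), sd = 0.2)
  m$classes <- c("a", "b", "c")
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  m2 <- load_checkpoint(path)
  expect_identical(m2$classes, m$classes)
  expect_identical(m2$config, m$config)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_identical(model_forward(m2, img), model_forward(m, img))
})
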