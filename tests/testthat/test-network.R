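test_that("the architecture invariants are enforced at spec level", {
  spec <- kromnet_spec(4L, 64L, "small")
  expect_s3_class(spec, "kromnet_spec")
  bad <- spec
  bad$conv_blocks <- bad$conv_blocks[1:5]
  expect_error(validate_kromnet_spec(bad), "6 conv")
  bad <- spec
  bad$dilated_blocks[[1]]$out_channels <- 30L  # 16 does not divide 30
  expect_error(validate_kromnet_spec(bad), "reduction_ratio")
  bad <- spec
  bad$dilated_blocks[[2]]$dilation <- 0L
  expect_error(validate_kromnet_spec(bad), "dilation")
  expect_error(kromnet_spec(5L), "num_classes")
})

test_that("global average pooling equals the scalar loop oracle", {
  const <- array(7, c(3, 5, 2))
  expect_equal(global_avg_pool(const), c(7, 7))
  m <- array(0, c(2, 2, 1)); m[, , 1] <- matrix(c(1, 2, 3, 4), 2, 2)
  expect_equal(global_avg_pool(m), 2.5)
  set.seed(8)
  x <- array(rnorm(4 * 4 * 3), c(4, 4, 3))
  expect_equal(global_avg_pool(x), oracle_gap(x), tolerance = 1e-6)
  expect_error(global_avg_pool(array(0, c(0, 2, 1))), "spatial")
})

test_that("attention weights follow the bottleneck-sigmoid chain", {
  C <- 8L
  W1z <- matrix(0, C, C / 2); W2z <- matrix(0, C / 2, C)
  expect_equal(attention_weights(rnorm(C), W1z, W2z), rep(0.5, C))
  set.seed(2)
  W1 <- matrix(rnorm(C * C / 2, 0, 0.5), C)
  W2 <- matrix(rnorm(C * C / 2, 0, 0.5), C / 2)
  M2 <- rnorm(C)
  got <- attention_weights(M2, W1, W2)
  expect_true(all(got > 0 & got < 1))
  manual <- 1 / (1 + exp(-(pmax(0, as.vector(M2 %*% W1)) %*% W2)))
  expect_equal(got, as.vector(manual), tolerance = 1e-6)
  expect_error(attention_weights(rnorm(4), W1, W2), "channel")
})

test_that("recalibration is an exact channel-wise product", {
  set.seed(3)
  M1 <- array(rnorm(4 * 4 * 6), c(4, 4, 6))
  expect_equal(recalibrate(M1, rep(1, 6)), M1)
  expect_true(all(recalibrate(M1, rep(0, 6)) == 0))
  w <- runif(6)
  got <- recalibrate(M1, w)
  for (c in 1:6) expect_equal(got[, , c], w[c] * M1[, , c])
  expect_error(recalibrate(M1, rep(1, 5)), "mismatch")
  # attention is a contraction: weights < 1 shrink every channel
  expect_true(all(abs(got) <= abs(M1)))
})

test_that("dilated convolution preserves size and collapses to standard at rate 1", {
  set.seed(4)
  for (r in 1:10) {
    x <- matrix(rnorm(64), 8, 8)
    k <- matrix(rnorm(9), 3, 3)
    expect_lt(max(abs(dilated_conv(x, k, 1L) - oracle_conv2d(x, k, 1L))),
              1e-10)
    expect_identical(dim(dilated_conv(x, k, 2L)), c(8L, 8L))
    expect_lt(max(abs(dilated_conv(x, k, 2L) - oracle_conv2d(x, k, 2L))),
              1e-10)
  }
  # 1x1 input, 3x3 kernel, rate 2: every off-center tap falls on padding
  x1 <- matrix(5, 1, 1)
  k <- matrix(1:9, 3, 3)
  expect_equal(dilated_conv(x1, k, 2L)[1, 1], k[2, 2] * 5)
  expect_error(dilated_conv(x1, k, 0L), "rate")
})

test_that("softmax rows are normalized even for extreme logits", {
  z <- rbind(c(1e4, -1e4, 0, 5), c(-1e4, -1e4, -1e4, -1e4),
             c(0.1, 0.2, 0.3, 0.4))
  p <- kromnet:::softmax(z)
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  expect_true(all(p >= 0))
})

test_that("built models emit class probabilities of the requested width", {
  spec4 <- kromnet_spec(4L, 32L, "small")
  m4 <- build_kromnet(spec4, seed = 21)
  x <- array(runif(32 * 32 * 5), c(32, 32, 5, 1))
  p <- predict(m4, x)
  expect_identical(dim(p), c(5L, 4L))
  expect_true(all(abs(rowSums(p) - 1) < 1e-6))
  m6 <- build_kromnet(kromnet_spec(6L, 32L, "small"), seed = 21)
  expect_identical(ncol(predict(m6, x)), 6L)
  # seeded init reproducibility
  expect_identical(build_kromnet(spec4, seed = 21), m4)
})

test_that("spatial size survives every dilated block", {
  m <- build_kromnet(kromnet_spec(4L, 32L, "small"), seed = 1)
  x <- array(runif(32 * 32 * 2), c(32, 32, 2, 1))
  fwd <- kromnet:::kromnet_forward(m, x, keep_cache = TRUE)
  conv_idx <- which(vapply(m$layers, function(l) l$type == "conv", logical(1)))
  dil_idx <- conv_idx[vapply(m$layers[conv_idx], function(l) l$dil > 1L,
                             logical(1))]
  expect_length(dil_idx, 2L)
  for (i in dil_idx) {
    cache <- fwd$caches[[i]]
    expect_identical(dim(cache$pre)[1:2], cache$conv$dims[1:2])
  }
})

test_that("cross-entropy matches its closed forms and the double-sum oracle", {
  perfect <- prediction_batch(diag(4), diag(4))
  expect_equal(cross_entropy(perfect), 0)
  u4 <- prediction_batch(matrix(1 / 4, 3, 4), onehot_encode(c(0L, 1L, 3L), 4))
  expect_equal(cross_entropy(u4), log(4), tolerance = 1e-5)
  u6 <- prediction_batch(matrix(1 / 6, 2, 6), onehot_encode(c(2L, 5L), 6))
  expect_equal(cross_entropy(u6), log(6), tolerance = 1e-5)
  set.seed(6)
  for (r in 1:10) {
    z <- matrix(rnorm(5 * 4, sd = 2), 5, 4)
    p <- kromnet:::softmax(z)
    y <- onehot_encode(sample(0:3, 5, replace = TRUE), 4)
    b <- prediction_batch(p, y)
    expect_equal(cross_entropy(b), oracle_cross_entropy(p, y),
                 tolerance = 1e-6)
  }
  expect_error(prediction_batch(matrix(0.5, 2, 4), onehot_encode(c(0L, 1L), 4)),
               "sum to 1")
})

test_that("analytic gradients agree with finite differences end to end", {
  spec <- kromnet_spec(4L, 16L, "small",
                       conv_channels = c(2, 2, 2, 2, 2, 4),
                       dilated_channels = c(4, 4), fc_hidden = 8,
                       reduction_ratio = 2L)
  m <- build_kromnet(spec, seed = 11)
  set.seed(5)
  x <- array(runif(16 * 16 * 3), c(16, 16, 3, 1))
  y <- onehot_encode(c(0L, 2L, 3L), 4L)
  expect_lt(gradcheck_worst(m, x, y, n_per_param = 4L), 1e-4)
})

test_that("a spec survives the YAML roundtrip", {
  spec <- kromnet_spec(6L, 64L, "small")
  f <- withr::local_tempfile(fileext = ".yaml")
  write_kromnet_spec(spec, f)
  back <- read_kromnet_spec(f)
  expect_identical(back$fc_widths, spec$fc_widths)
  expect_identical(back$num_classes, spec$num_classes)
  expect_identical(build_kromnet(back, 7L), build_kromnet(spec, 7L))
})
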