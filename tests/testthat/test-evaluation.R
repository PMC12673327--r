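test_that("confusion counts match a brute-force tally", {
  cm <- confusion(c(0L, 1L, 2L, 3L), c(0L, 1L, 2L, 3L), 4L)
  expect_true(all(cm$counts == diag(c(1, 1, 1, 1))))
  one <- confusion(3L, 0L, 4L)
  expect_identical(unname(one$counts[1, 4]), 1L)
  expect_identical(sum(one$counts), 1L)
  set.seed(17)
  for (r in 1:30) {
    K <- sample(2:6, 1)
    n <- sample(10:60, 1)
    true <- sample(0:(K - 1), n, replace = TRUE)
    pred <- sample(0:(K - 1), n, replace = TRUE)
    cm <- confusion(pred, true, K)
    for (i in 0:(K - 1)) for (j in 0:(K - 1))
      expect_identical(unname(cm$counts[i + 1, j + 1]),
                       sum(true == i & pred == j))
    # per class, TP + FP + FN + TN covers every record
    expect_true(all(cm$tp + cm$fp + cm$fn + cm$tn == n))
  }
  expect_error(confusion(c(0L, 4L), c(0L, 1L), 4L), "labels")
  expect_error(confusion(0L, c(0L, 1L), 4L), "equal length")
})

test_that("metrics reproduce hand-derived values", {
  ident <- confusion(rep(0:3, each = 10), rep(0:3, each = 10), 4L)
  rep1 <- compute_metrics(ident)
  expect_equal(rep1$precision, 1)
  expect_equal(rep1$recall, 1)
  expect_equal(rep1$f1, 1)
  expect_equal(rep1$accuracy, 100)

  # counts ((8,2),(1,9)): accuracy 85%, class-0 P 8/9, R 8/10
  true <- rep(c(0L, 1L), c(10L, 10L))
  pred <- c(rep(0L, 8), rep(1L, 2), rep(0L, 1), rep(1L, 9))
  cm <- confusion(pred, true, 2L)
  r <- compute_metrics(cm)
  expect_equal(r$accuracy, 85)
  expect_equal(r$per_class$precision[1], 8 / 9)
  expect_equal(r$per_class$recall[1], 8 / 10)
  expect_equal(r$precision, (8 / 9 + 9 / 11) / 2, tolerance = 1e-4)
  expect_equal(round(r$precision, 4), 0.8535)

  wrong <- confusion(c(1L, 0L), c(0L, 1L), 2L)
  rw <- suppressWarnings(compute_metrics(wrong))
  expect_equal(rw$accuracy, 0)
  expect_equal(rw$recall, 0)
})

test_that("metrics match the counting oracle and ignore sample order", {
  set.seed(23)
  for (r in 1:20) {
    K <- sample(c(2L, 4L, 6L), 1)
    n <- sample(30:80, 1)
    true <- sample(0:(K - 1), n, replace = TRUE)
    pred <- sample(0:(K - 1), n, replace = TRUE)
    got <- suppressWarnings(compute_metrics(confusion(pred, true, K)))
    want <- oracle_metrics(pred, true, K)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
    expect_equal(got$f1, want$f1, tolerance = 1e-12)
    expect_equal(got$accuracy, want$accuracy, tolerance = 1e-12)
    perm <- sample(n)
    got2 <- suppressWarnings(compute_metrics(confusion(pred[perm], true[perm], K)))
    expect_equal(got2$f1, got$f1)
    expect_equal(got2$accuracy, got$accuracy)
  }
})

test_that("zero-division classes contribute zero with a warning", {
  # class 1 never predicted and never true -> both denominators empty
  cm <- confusion(c(0L, 0L, 2L), c(0L, 0L, 2L), 3L)
  w <- capture_warnings(r <- compute_metrics(cm))
  expect_true(any(grepl("zero denominator", w)))
  expect_equal(r$per_class$precision[2], 0)
  expect_equal(r$per_class$recall[2], 0)
  expect_equal(r$accuracy, 100)
})

test_that("reports render with the documented CSV formatting", {
  d <- withr::local_tempdir()
  cm <- confusion(rep(0:3, each = 5), rep(0:3, each = 5), 4L)
  rep1 <- compute_metrics(cm)
  write_report(rep1, cm, d)
  lines <- readLines(file.path(d, "metrics.csv"))
  expect_identical(lines[1], "class,precision,recall,f1,support")
  expect_identical(lines[2], "0,1.0000,1.0000,1.0000,5")
  expect_identical(lines[6], "macro,1.0000,1.0000,1.0000,20")
  expect_identical(lines[9], "accuracy_percent,100.00,,,")
  expect_true(file.exists(file.path(d, "confusion.csv")))
  expect_true(file.exists(file.path(d, "confusion.png")))
  # rerun is byte-identical
  before <- readBin(file.path(d, "metrics.csv"), "raw", 1e5)
  write_report(rep1, cm, d)
  expect_identical(readBin(file.path(d, "metrics.csv"), "raw", 1e5), before)
  # six-class report has six per-class rows
  cm6 <- confusion(rep(0:5, each = 2), rep(0:5, each = 2), 6L)
  d6 <- withr::local_tempdir()
  write_report(compute_metrics(cm6), cm6, d6)
  expect_length(grep("^[0-9],", readLines(file.path(d6, "metrics.csv"))), 6L)
})

test_that("attention maps expose sigmoid weights and match a recomputation", {
  m <- build_kromnet(kromnet_spec(4L, 32L, "small"), seed = 4L)
  img <- matrix(as.numeric(matrix(runif(32 * 32), 32) > 0.6), 32, 32)
  maps <- export_attention_maps(m, img)
  expect_length(maps, 2L)
  for (a in maps) {
    expect_true(all(a$weights > 0 & a$weights < 1))
    expect_identical(dim(a$overlay), c(32L, 32L))
    expect_true(all(a$overlay >= 0 & a$overlay <= 1))
  }
  # zeroed attention parameters give flat 0.5 weights
  mz <- m
  for (i in seq_along(mz$layers)) {
    if (mz$layers[[i]]$type == "attn") {
      mz$layers[[i]]$W1[] <- 0; mz$layers[[i]]$W2[] <- 0
      mz$layers[[i]]$b1[] <- 0; mz$layers[[i]]$b2[] <- 0
    }
  }
  maps0 <- export_attention_maps(mz, img)
  for (a in maps0) expect_equal(a$weights, rep(0.5, length(a$weights)))
  # the exported vector equals attention_weights() on the pooled input
  x4 <- img; dim(x4) <- c(32L, 32L, 1L, 1L)
  fwd <- kromnet:::kromnet_forward(m, x4, keep_cache = TRUE)
  att_idx <- which(vapply(m$layers, function(l) l$type == "attn", logical(1)))
  for (j in seq_along(att_idx)) {
    l <- m$layers[[att_idx[j]]]
    cache <- fwd$caches[[att_idx[j]]]
    hin <- cache$input
    M1 <- array(hin[, , 1, ], dim(hin)[c(1, 2, 4)])
    want <- attention_weights(global_avg_pool(M1), l$W1, l$W2, l$b1, l$b2)
    expect_equal(maps[[j]]$weights, want, tolerance = 1e-6)
  }
  nomodel <- build_kromnet(kromnet_spec(4L, 32L, "small"), 1L)
  nomodel$layers <- Filter(function(l) l$type != "attn", nomodel$layers)
  expect_error(export_attention_maps(nomodel, img), "attention")
})
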