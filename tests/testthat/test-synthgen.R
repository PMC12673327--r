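test_that("pose coordinates encode the flexion angle exactly", {
  set.seed(1)
  for (r in 1:40) {
    ang <- runif(1, 0, 150)
    pose <- limb_pose(ang, sample(c("flexion", "extension"), 1),
                      thigh_len = runif(1, 32, 45),
                      shank_len = runif(1, 32, 45),
                      global_rotation = runif(1, -10, 10),
                      translation = runif(2, -8, 8), seed = r)
    expect_lt(abs(pose_flexion_from_coords(pose) - ang), 1e-6)
  }
})

test_that("pose construction enforces its invariants", {
  expect_error(limb_pose(160), "flexion_angle")
  expect_error(limb_pose(90, thigh_len = -1), "positive")
  expect_error(limb_pose(90, background_level = 100, foreground_level = 120),
               "gap")
  expect_error(limb_pose(90, occlusion_fraction = 0.5), "occlusion_fraction")
})

test_that("sampled poses realize their target label under each scheme", {
  p <- sample_pose("four_class", 0L, 7)
  expect_gte(p$flexion_angle, 125)
  expect_identical(p$pose_type, "flexion")
  for (s in c(3, 19, 101)) {
    p2 <- sample_pose("four_class", 2L, s)
    expect_lte(p2$flexion_angle, 0.5)
    expect_identical(p2$pose_type, "extension")
  }
  # label consistency over many draws, both schemes
  set.seed(42)
  for (r in 1:500) {
    lab <- sample(0:3, 1)
    p <- sample_pose("four_class", lab, r)
    expect_identical(assign_four_class(p$flexion_angle, p$pose_type), lab)
  }
  for (r in 1:500) {
    lab <- sample(0:5, 1)
    p <- sample_pose("six_class", lab, r + 1000L)
    expect_identical(assign_six_class(p$flexion_angle), lab)
  }
})

test_that("identical scheme/label/seed inputs give identical poses", {
  a <- sample_pose("six_class", 4L, 123)
  b <- sample_pose("six_class", 4L, 123)
  expect_identical(a, b)
})

test_that("invalid schemes and labels are rejected by name", {
  expect_error(sample_pose("five_class", 0L, 1), "five_class")
  expect_error(sample_pose("four_class", 4L, 1), "4")
  expect_error(sample_pose("six_class", -1, 1), "-1")
})

test_that("four-class assignment follows the clinical thresholds", {
  expect_identical(assign_four_class(125.0, "flexion"), 0L)
  expect_identical(assign_four_class(124.999, "flexion"), 1L)
  expect_identical(assign_four_class(0.0, "extension"), 2L)
  expect_identical(assign_four_class(5.0, "extension"), 3L)
  expect_identical(assign_four_class(0.5, "extension"), 2L)  # zero tolerance
  expect_identical(assign_four_class(150, "flexion"), 0L)
})

test_that("six-class assignment is nearest-nominal with midpoint edges", {
  expect_identical(assign_six_class(25.0), 1L)
  expect_identical(assign_six_class(30.0), 1L)   # |30-25| < |30-50|
  expect_identical(assign_six_class(140.0), 5L)  # above 125 -> 125 class
  expect_identical(assign_six_class(0), 0L)
  expect_identical(assign_six_class(12.5), 1L)   # edge -> upper bin
  expect_identical(assign_six_class(c(12.4, 62.5, 112.4)), c(0L, 3L, 4L))
})

test_that("a straight leg renders with collinear joints", {
  pose <- limb_pose(0, "extension", seed = 3)
  v1 <- pose$hip_xy - pose$knee_xy
  v2 <- pose$ankle_xy - pose$knee_xy
  cross <- v1[1] * v2[2] - v1[2] * v2[1]
  expect_lt(abs(cross) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2))), 1e-9)
  img <- render_limb(pose)
  expect_identical(dim(img), c(128L, 128L))
})

test_that("rendering is deterministic and refuses out-of-canvas limbs", {
  pose <- sample_pose("four_class", 1L, 99)
  expect_identical(render_limb(pose), render_limb(pose))
  far <- limb_pose(90, "flexion", translation = c(60, 60), seed = 1)
  expect_error(render_limb(far), "canvas")
})

test_that("generated datasets honor counts, labels, and determinism", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  counts <- c(5L, 4L, 3L, 4L)
  m1 <- generate_dataset("four_class", counts, d1, global_seed = 11L,
                         canvas = 96L)
  expect_identical(m1$class_counts, counts)
  expect_identical(nrow(m1$records), 16L)
  expect_false(anyDuplicated(m1$records$id) > 0)
  # relabelling from the stored angle reproduces the manifest labels
  expect_identical(assign_four_class(m1$records$angle_deg,
                                     m1$records$pose_type),
                   m1$records$label4)
  expect_identical(assign_six_class(m1$records$angle_deg), m1$records$label6)
  # byte-identical regeneration
  m2 <- generate_dataset("four_class", counts, d2, global_seed = 11L,
                         canvas = 96L)
  expect_identical(readLines(file.path(d1, "manifest.csv")),
                   readLines(file.path(d2, "manifest.csv")))
  f1 <- file.path(d1, m1$records$path)
  f2 <- file.path(d2, m2$records$path)
  for (i in seq_along(f1))
    expect_identical(readBin(f1[i], "raw", 1e5), readBin(f2[i], "raw", 1e5))
  # manifest roundtrip
  mr <- read_manifest(file.path(d1, "manifest.csv"), "four_class")
  expect_identical(mr$records$label4, m1$records$label4)
  expect_equal(mr$records$angle_deg, m1$records$angle_deg, tolerance = 1e-9)
})

test_that("zero-count requests give an empty manifest and no images", {
  d <- withr::local_tempdir()
  m <- generate_dataset("four_class", c(0L, 0L, 0L, 0L), d)
  expect_identical(nrow(m$records), 0L)
  expect_length(list.files(file.path(d, "images")), 0L)
})

test_that("Otsu isolates nearly all true limb pixels on clean renders", {
  set.seed(7)
  for (r in 1:15) {
    pose <- sample_pose("four_class", sample(0:3, 1), r, clean = TRUE)
    img <- render_limb(pose)
    true_mask <- img > (pose$background_level + pose$foreground_level) / 2
    bw <- binarize_otsu(img)
    got <- bw$pixels == bw$maxval
    expect_gte(sum(got & true_mask) / sum(true_mask), 0.95)
  }
})

test_that("the silhouette-fit oracle recovers the flexion angle within 1 degree", {
  # noiseless renders across the full angular range, geometry nuisance on
  set.seed(99)
  angs <- round(c(0, 150, seq(0.5, 149.5, length.out = 98)), 3)
  errs <- numeric(length(angs))
  for (i in seq_along(angs)) {
    pose <- limb_pose(angs[i],
                      pose_type = if (angs[i] > 50) "flexion" else "extension",
                      thigh_len = runif(1, 32, 45),
                      shank_len = runif(1, 32, 45),
                      limb_halfwidth = runif(1, 5, 10),
                      global_rotation = runif(1, -10, 10),
                      translation = runif(2, -8, 8), seed = i)
    img <- render_limb(pose)
    mask <- matrix(as.numeric(
      img > (pose$background_level + pose$foreground_level) / 2), 128, 128)
    errs[i] <- abs(oracle_fit_flexion(mask) - angs[i])
  }
  expect_identical(sum(errs <= 1), length(angs))
})
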