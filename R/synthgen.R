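# Label scheme constants: clinical ROM thresholds (KSS-derived).
.FOUR_CLASS_NAMES <- c("standard_flexion", "substandard_flexion",
                       "standard_extension", "substandard_extension")
.SIX_CLASS_NOMINALS <- c(0, 25, 50, 75, 100, 125)
.SIX_CLASS_EDGES <- c(12.5, 37.5, 62.5, 87.5, 112.5)
.EXTENSION_ZERO_TOL <- 0.5  # degrees; "ROM = 0" applied with tolerance

.check_scheme <- function(scheme) {
  if (!is.character(scheme) || length(scheme) != 1L ||
      !scheme %in% c("four_class", "six_class")) {
    stop("unknown label scheme: ", deparse(scheme),
         " (expected \"four_class\" or \"six_class\")", call. = FALSE)
  }
  scheme
}

.n_classes <- function(scheme) if (scheme == "four_class") 4L else 6L

#' Construct the geometric ground truth for one synthetic knee image
#'
#' A `limb_pose` idealizes the acquisition setting: a supine patient's
#' isolated lower limb photographed side-on, thigh and shank modelled as two
#' thick segments (capsules) hinged at the knee. The knee flexion angle is
#' 0 deg for a fully straight leg and grows as the knee bends, so the
#' interior angle at the knee vertex equals `180 - flexion_angle`.
#'
#' Joint coordinates are derived from the angular parameters: the knee sits
#' at the canvas centre plus `translation`; the thigh points "outward"
#' (rotated by `global_rotation`) and the shank direction closes the
#' interior angle.
#'
#' @param flexion_angle Knee flexion in degrees, in `[0, 150]`.
#' @param pose_type `"flexion"` or `"extension"`: which maximal-effort
#'   attempt the photograph simulates.
#' @param thigh_len,shank_len Segment lengths in pixels (positive).
#' @param limb_halfwidth Capsule half-width in pixels.
#' @param global_rotation Whole-limb rotation in degrees.
#' @param translation Length-2 pixel offset of the knee from canvas centre.
#' @param background_level,foreground_level 8-bit intensities; must differ
#'   by at least 40 so Otsu thresholding stays separable.
#' @param noise_sd Additive Gaussian noise standard deviation (intensity).
#' @param blur_radius Gaussian blur sigma in pixels.
#' @param occlusion_fraction Fraction of limb pixels covered by a
#'   background-coloured rectangle, in `[0, 0.3]`.
#' @param seed Integer seed governing the stochastic rendering stages.
#' @param canvas Canvas side in pixels used to place the knee.
#' @return An object of class `limb_pose` with joint coordinates
#'   `hip_xy`, `knee_xy`, `ankle_xy` (x = column, y = row) and all nuisance
#'   fields.
#' @export
limb_pose <- function(flexion_angle, pose_type = c("flexion", "extension"),
                      thigh_len = 40, shank_len = 40, limb_halfwidth = 8,
                      global_rotation = 0, translation = c(0, 0),
                      background_level = 40, foreground_level = 200,
                      noise_sd = 0, blur_radius = 0, occlusion_fraction = 0,
                      seed = 1L, canvas = 128L) {
  pose_type <- match.arg(pose_type)
  stopifnot(length(flexion_angle) == 1L, is.finite(flexion_angle))
  if (flexion_angle < 0 || flexion_angle > 150)
    stop("flexion_angle must lie in [0, 150], got ", flexion_angle)
  if (thigh_len <= 0 || shank_len <= 0)
    stop("segment lengths must be positive")
  if (abs(foreground_level - background_level) < 40)
    stop("foreground/background intensity gap must be >= 40 (got ",
         abs(foreground_level - background_level), ")")
  if (occlusion_fraction < 0 || occlusion_fraction > 0.3)
    stop("occlusion_fraction must lie in [0, 0.3]")

  knee <- c(canvas / 2, canvas / 2) + translation
  unit <- function(deg) c(cos(deg * pi / 180), sin(deg * pi / 180))
  theta_thigh <- 180 + global_rotation
  # interior angle at knee = 180 - flexion
  theta_shank <- theta_thigh + (180 - flexion_angle)
  hip <- knee + thigh_len * unit(theta_thigh)
  ankle <- knee + shank_len * unit(theta_shank)

  pose <- structure(list(
    hip_xy = hip, knee_xy = knee, ankle_xy = ankle,
    flexion_angle = flexion_angle, pose_type = pose_type,
    thigh_len = thigh_len, shank_len = shank_len,
    limb_halfwidth = limb_halfwidth, global_rotation = global_rotation,
    translation = translation, background_level = background_level,
    foreground_level = foreground_level, noise_sd = noise_sd,
    blur_radius = blur_radius, occlusion_fraction = occlusion_fraction,
    seed = as.integer(seed), canvas = as.integer(canvas)
  ), class = "limb_pose")

  # invariant: stored coordinates reproduce the flexion angle
  stopifnot(abs(pose_flexion_from_coords(pose) - flexion_angle) < 1e-6)
  pose
}

#' Recompute the flexion angle from a pose's stored joint coordinates
#'
#' Returns 180 degrees minus the interior angle at the knee vertex formed by
#' the hip and ankle coordinates.
#'
#' @param pose A `limb_pose`.
#' @return Flexion angle in degrees.
#' @export
pose_flexion_from_coords <- function(pose) {
  u <- pose$hip_xy - pose$knee_xy
  v <- pose$ankle_xy - pose$knee_xy
  ct <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  interior <- acos(pmin(1, pmax(-1, ct))) * 180 / pi
  180 - interior
}

#' @export
print.limb_pose <- function(x, ...) {
  cat(sprintf("<limb_pose> %s attempt, flexion %.3f deg, seed %d\n",
              x$pose_type, x$flexion_angle, x$seed))
  invisible(x)
}

# Draw a flexion angle (deg, already rounded to 3 decimals) realizing a
# target label. Attempt-angle ranges are a documented design choice:
# flexion attempts from [60, 150], extension attempts from [0, 40].
.sample_angle <- function(scheme, target_label) {
  if (scheme == "four_class") {
    ang <- switch(as.character(target_label),
      "0" = stats::runif(1, 125, 150),
      "1" = stats::runif(1, 60, 124.998),
      "2" = stats::runif(1, 0, .EXTENSION_ZERO_TOL - 0.002),
      "3" = stats::runif(1, 0.6, 40))
  } else {
    lo <- c(0, .SIX_CLASS_EDGES)[target_label + 1L] + 0.002
    hi <- c(.SIX_CLASS_EDGES, 150)[target_label + 1L] - 0.002
    ang <- stats::runif(1, lo, hi)
  }
  round(ang, 3)
}

#' Sample a labelled synthetic limb pose
#'
#' Draws a flexion angle consistent with `target_label` under the given
#' label scheme, plus all nuisance parameters (segment lengths, limb
#' thickness, global rotation, translation, intensities, blur, noise,
#' occlusion) from fixed documented distributions, seeded by `rng_seed`.
#' Flexion-attempt angles come from the high range `[60, 150]`,
#' extension-attempt angles from `[0, 40]`.
#'
#' @param scheme `"four_class"` or `"six_class"`.
#' @param target_label Integer class id in `[0, K-1]`.
#' @param rng_seed Integer seed; identical inputs always return an
#'   identical pose.
#' @param clean If `TRUE`, zero out noise, blur and occlusion (geometric
#'   nuisance is kept); used for noiseless fixtures.
#' @param canvas Canvas side in pixels.
#' @return A [limb_pose()].
#' @export
sample_pose <- function(scheme, target_label, rng_seed, clean = FALSE,
                        canvas = 128L) {
  scheme <- .check_scheme(scheme)
  K <- .n_classes(scheme)
  if (!is.numeric(target_label) || length(target_label) != 1L ||
      is.na(target_label) || target_label != as.integer(target_label) ||
      target_label < 0 || target_label >= K) {
    stop("invalid label for scheme ", scheme, ": ", deparse(target_label))
  }
  target_label <- as.integer(target_label)

  withr::with_seed(as.integer(rng_seed), {
    ang <- .sample_angle(scheme, target_label)
    if (scheme == "four_class") {
      pt <- if (target_label <= 1L) "flexion" else "extension"
    } else {
      pt <- if (ang >= 37.5) "flexion" else "extension"
    }
    bg <- sample(10:80, 1)
    fg <- min(250, bg + sample(90:175, 1))
    occl <- if (stats::runif(1) < 0.5) 0 else stats::runif(1, 0.05, 0.25)
    sc <- canvas / 128  # canvas acts as a resolution knob; geometry scales
    limb_pose(
      flexion_angle = ang, pose_type = pt,
      thigh_len = sc * stats::runif(1, 32, 45),
      shank_len = sc * stats::runif(1, 32, 45),
      limb_halfwidth = sc * stats::runif(1, 5, 10),
      global_rotation = stats::runif(1, -10, 10),
      translation = sc * stats::runif(2, -8, 8),
      background_level = bg, foreground_level = fg,
      noise_sd = if (clean) 0 else stats::runif(1, 0, 6),
      blur_radius = if (clean) 0 else stats::runif(1, 0, 1.2),
      occlusion_fraction = if (clean) 0 else occl,
      seed = as.integer(rng_seed), canvas = canvas)
  })
}

# squared distance from pixel centres (px, py vectors) to segment p0-p1
.dist_to_segment <- function(px, py, p0, p1) {
  wx <- p1[1] - p0[1]; wy <- p1[2] - p0[2]
  len2 <- wx * wx + wy * wy
  t <- ((px - p0[1]) * wx + (py - p0[2]) * wy) / len2
  t <- pmin(1, pmax(0, t))
  dx <- px - (p0[1] + t * wx); dy <- py - (p0[2] + t * wy)
  sqrt(dx * dx + dy * dy)
}

#' Render a limb pose to a grayscale image
#'
#' Draws the thigh and shank as two overlapping capsule silhouettes meeting
#' at the knee, composited over a uniform background, then (in this fixed
#' order) Gaussian-blurred, corrupted with additive Gaussian noise,
#' partially occluded by a background-coloured rectangle, and clamped to
#' `[0, 255]`. All stochastic stages are seeded from `pose$seed`, so the
#' same pose always renders to a bit-identical image.
#'
#' @param pose A [limb_pose()].
#' @param height,width Canvas size in pixels.
#' @return Integer matrix (`height` x `width`, row = y) with values 0-255.
#' @export
render_limb <- function(pose, height = pose$canvas, width = pose$canvas) {
  hw <- pose$limb_halfwidth
  pts <- rbind(pose$hip_xy, pose$knee_xy, pose$ankle_xy)
  if (any(pts[, 1] < 0.5 + 0) || any(pts[, 1] > width + 0.5) ||
      any(pts[, 2] < 0.5) || any(pts[, 2] > height + 0.5) ||
      any(pts[, 1] - hw < 0) || any(pts[, 1] + hw > width + 1) ||
      any(pts[, 2] - hw < 0) || any(pts[, 2] + hw > height + 1)) {
    stop("limb extends outside the canvas after transform; ",
         "refusing to crop the knee region")
  }

  px <- matrix(rep(seq_len(width), each = height), nrow = height)   # x = col
  py <- matrix(rep(seq_len(height), times = width), nrow = height)  # y = row
  d1 <- .dist_to_segment(px, py, pose$knee_xy, pose$hip_xy)
  d2 <- .dist_to_segment(px, py, pose$knee_xy, pose$ankle_xy)
  mask <- (pmin(d1, d2) <= hw)

  img <- matrix(pose$background_level, height, width)
  img[mask] <- pose$foreground_level

  withr::with_seed(pose$seed, {
    if (pose$blur_radius > 0.05)
      img <- EBImage::gblur(img, sigma = pose$blur_radius)
    if (pose$noise_sd > 0)
      img <- img + matrix(stats::rnorm(height * width, 0, pose$noise_sd),
                          height, width)
    if (pose$occlusion_fraction > 0 && any(mask)) {
      area <- pose$occlusion_fraction * sum(mask)
      centre <- which(mask, arr.ind = TRUE)[sample(sum(mask), 1), ]
      aspect <- stats::runif(1, 0.5, 2)
      hh <- max(1L, round(sqrt(area * aspect)))
      ww <- max(1L, round(area / hh))
      r0 <- max(1L, centre[1] - hh %/% 2L); r1 <- min(height, r0 + hh - 1L)
      c0 <- max(1L, centre[2] - ww %/% 2L); c1 <- min(width, c0 + ww - 1L)
      img[r0:r1, c0:c1] <- pose$background_level
    }
  })
  matrix(as.integer(round(pmin(255, pmax(0, img)))), height, width)
}

#' Assign the four-class clinical ROM label
#'
#' Clinical thresholds: a flexion attempt is "standard" (label 0) when the
#' flexion angle reaches 125 degrees, otherwise "substandard" (label 1); an
#' extension attempt is "standard" (label 2) when the residual flexion is
#' zero -- applied with a 0.5 degree tolerance for continuous synthetic
#' angles -- otherwise "substandard" (label 3). Label coding 0-3.
#'
#' @param flexion_angle Angle(s) in degrees, in `[0, 150]`.
#' @param pose_type `"flexion"` or `"extension"` (recycled).
#' @return Integer label(s) in 0-3.
#' @export
assign_four_class <- function(flexion_angle, pose_type) {
  stopifnot(all(flexion_angle >= 0 & flexion_angle <= 150))
  pose_type <- rep_len(pose_type, length(flexion_angle))
  stopifnot(all(pose_type %in% c("flexion", "extension")))
  ifelse(pose_type == "flexion",
         ifelse(flexion_angle >= 125, 0L, 1L),
         ifelse(flexion_angle <= .EXTENSION_ZERO_TOL, 2L, 3L))
}

#' Assign the six-class ROM label
#'
#' Classes correspond to nominal angles 0, 25, 50, 75, 100 and 125 degrees;
#' an angle is assigned to the nearest nominal value (bin edges at the
#' midpoints 12.5, 37.5, 62.5, 87.5, 112.5; angles above 125 fall in the
#' 125-degree class). An angle exactly on an edge belongs to the upper bin.
#'
#' @param flexion_angle Angle(s) in degrees, in `[0, 150]`.
#' @return Integer label(s) in 0-5.
#' @export
assign_six_class <- function(flexion_angle) {
  stopifnot(all(flexion_angle >= 0 & flexion_angle <= 150))
  findInterval(flexion_angle, .SIX_CLASS_EDGES)
}

.record_seed <- function(global_seed, index) {
  as.integer((as.numeric(global_seed) * 1000003 + index * 7919) %% 2147483647)
}

#' Generate a labelled synthetic knee-image dataset
#'
#' Writes one 8-bit grayscale PNG per record plus a CSV manifest with
#' header `id,path,pose_type,angle_deg,label4,label6,split`. Per-record
#' seeds are derived deterministically from `global_seed` and the record
#' index, so regeneration is byte-identical and order-stable.
#'
#' @param scheme `"four_class"` or `"six_class"`; decides which label each
#'   requested count refers to (both labels are stored for every record).
#' @param class_counts Integer vector of length K: images per class.
#' @param out_dir Output directory (created if needed).
#' @param global_seed Integer master seed.
#' @param canvas Canvas side in pixels.
#' @param clean Propagated to [sample_pose()]: `TRUE` renders noiseless,
#'   unoccluded images.
#' @return A `dataset_manifest`: list with `records` (data frame),
#'   `scheme`, `class_counts`, `global_seed`, `dir`.
#' @export
generate_dataset <- function(scheme, class_counts, out_dir,
                             global_seed = 1L, canvas = 128L, clean = FALSE) {
  scheme <- .check_scheme(scheme)
  K <- .n_classes(scheme)
  if (length(class_counts) != K || any(class_counts < 0) ||
      any(class_counts != as.integer(class_counts)))
    stop("class_counts must be ", K, " nonnegative integers for ", scheme)
  class_counts <- as.integer(class_counts)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)

  labels <- rep(seq_len(K) - 1L, class_counts)
  n <- length(labels)
  rec <- data.frame(id = character(n), path = character(n),
                    pose_type = character(n), angle_deg = numeric(n),
                    label4 = integer(n), label6 = integer(n),
                    split = character(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    pose <- sample_pose(scheme, labels[i], .record_seed(global_seed, i),
                        clean = clean, canvas = canvas)
    img <- render_limb(pose, canvas, canvas)
    id <- sprintf("img%05d", i)
    rel <- file.path("images", paste0(id, ".png"))
    dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
    png::writePNG(img / 255, file.path(out_dir, rel))
    rec$id[i] <- id; rec$path[i] <- rel
    rec$pose_type[i] <- pose$pose_type
    rec$angle_deg[i] <- pose$flexion_angle
    rec$label4[i] <- assign_four_class(pose$flexion_angle, pose$pose_type)
    rec$label6[i] <- assign_six_class(pose$flexion_angle)
    rec$split[i] <- "none"
  }
  lab_col <- if (scheme == "four_class") rec$label4 else rec$label6
  stopifnot(identical(as.integer(tabulate(lab_col + 1L, K)), class_counts))

  manifest <- structure(list(records = rec, scheme = scheme,
                             class_counts = class_counts,
                             global_seed = as.integer(global_seed),
                             dir = out_dir),
                        class = "dataset_manifest")
  write_manifest(manifest, file.path(out_dir, "manifest.csv"))
  manifest
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("<dataset_manifest> %s, %d records (%s), seed %d\n",
              x$scheme, nrow(x$records),
              paste(x$class_counts, collapse = "/"), x$global_seed))
  invisible(x)
}

#' Write a dataset manifest to CSV
#'
#' @param manifest A `dataset_manifest` or a records data frame.
#' @param path Output CSV path; angles are written with 3 decimals.
#' @export
write_manifest <- function(manifest, path) {
  rec <- if (inherits(manifest, "dataset_manifest")) manifest$records
         else manifest
  out <- rec
  out$angle_deg <- sprintf("%.3f", rec$angle_deg)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a dataset manifest CSV
#'
#' @param path Manifest CSV path.
#' @param scheme Label scheme to attach (used by splitting/training).
#' @param dir Dataset root for resolving image paths; defaults to the
#'   manifest's directory.
#' @return A `dataset_manifest`.
#' @export
read_manifest <- function(path, scheme = "four_class", dir = dirname(path)) {
  scheme <- .check_scheme(scheme)
  rec <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(id = "character", path = "character",
                                        pose_type = "character",
                                        angle_deg = "numeric",
                                        label4 = "integer",
                                        label6 = "integer",
                                        split = "character"))
  expected <- c("id", "path", "pose_type", "angle_deg",
                "label4", "label6", "split")
  if (!identical(names(rec), expected))
    stop("manifest header must be: ", paste(expected, collapse = ","))
  if (anyDuplicated(rec$id)) stop("duplicate record ids in manifest")
  K <- .n_classes(scheme)
  lab <- if (scheme == "four_class") rec$label4 else rec$label6
  structure(list(records = rec, scheme = scheme,
                 class_counts = as.integer(tabulate(lab + 1L, K)),
                 global_seed = NA_integer_, dir = dir),
            class = "dataset_manifest")
}

#' Labels of a manifest under its own scheme
#' @param manifest A `dataset_manifest`.
#' @return Integer vector of class ids.
#' @export
manifest_labels <- function(manifest) {
  if (manifest$scheme == "four_class") manifest$records$label4
  else manifest$records$label6
}
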