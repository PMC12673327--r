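#' Convert an image to 8-bit grayscale
#'
#' Three-channel input is reduced with the ITU-R BT.601 luminance weights
#' (0.299, 0.587, 0.114) and rounded half-up; single-channel input passes
#' through unchanged.
#'
#' @param image Either an `H x W` matrix (already grayscale) or an
#'   `H x W x 3` array, 8-bit values 0-255.
#' @return Integer `H x W` matrix with values 0-255.
#' @export
to_grayscale <- function(image) {
  if (is.matrix(image)) {
    return(matrix(as.integer(image), nrow(image), ncol(image)))
  }
  d <- dim(image)
  if (length(d) == 3L && d[3] == 1L) {
    return(matrix(as.integer(image[, , 1]), d[1], d[2]))
  }
  if (length(d) != 3L || d[3] != 3L) {
    stop("expected a single- or three-channel image, got dims ",
         paste(d, collapse = "x"))
  }
  g <- 0.299 * image[, , 1] + 0.587 * image[, , 2] + 0.114 * image[, , 3]
  matrix(as.integer(floor(g + 0.5)), d[1], d[2])  # round half-up
}

#' Otsu automatic threshold
#'
#' Returns the threshold `t` in `[0, 255]` maximizing the between-class
#' variance of the two pixel populations `{<= t}` and `{> t}` over the
#' 256-bin histogram. Ties are broken towards the smallest maximizing `t`.
#' A constant image returns that constant (every threshold is equivalent,
#' and this choice makes Eq.-style strict binarization map the image to all
#' zeros).
#'
#' @param gray Integer matrix/vector of 8-bit values with at least 1 pixel.
#' @return Integer threshold in `[0, 255]`.
#' @export
otsu_threshold <- function(gray) {
  v <- as.integer(gray)
  if (length(v) == 0L) stop("empty image")
  if (any(is.na(v)) || any(v < 0L | v > 255L))
    stop("pixel values must be integers in [0, 255]")
  u <- unique(v)
  if (length(u) == 1L) return(u)

  h <- tabulate(v + 1L, nbins = 256L)
  n <- length(v)
  lev <- 0:255
  w0 <- cumsum(h)                 # pixels <= t
  s0 <- cumsum(h * lev)           # intensity sum <= t
  stot <- s0[256]
  w1 <- n - w0
  mu0 <- ifelse(w0 > 0, s0 / w0, 0)
  mu1 <- ifelse(w1 > 0, (stot - s0) / w1, 0)
  sigma_b <- (w0 / n) * (w1 / n) * (mu0 - mu1)^2
  sigma_b[w0 == 0 | w1 == 0] <- 0
  as.integer(which.max(sigma_b) - 1L)   # which.max -> smallest maximizer
}

#' Binarize a grayscale image at a fixed threshold
#'
#' Pixels strictly exceeding `thresh` map to `maxval`; all others
#' (including pixels exactly equal to the threshold) map to 0.
#'
#' @param gray Integer `H x W` matrix, values 0-255.
#' @param thresh Threshold in `[0, 255]`.
#' @param maxval Output high value in `[1, 255]` (default 255).
#' @param source_id Optional record id carried through for provenance.
#' @return Object of class `binarized_image`: list with `pixels`
#'   (values in `{0, maxval}`), `threshold`, `maxval`, `source_id`.
#' @export
binarize <- function(gray, thresh, maxval = 255L, source_id = NULL) {
  if (inherits(gray, "binarized_image")) gray <- gray$pixels
  if (length(thresh) != 1L || thresh < 0 || thresh > 255 ||
      thresh != as.integer(thresh))
    stop("thresh must be an integer in [0, 255], got ", deparse(thresh))
  if (length(maxval) != 1L || maxval < 1 || maxval > 255 ||
      maxval != as.integer(maxval))
    stop("maxval must be an integer in [1, 255], got ", deparse(maxval))
  px <- matrix(ifelse(gray > thresh, as.integer(maxval), 0L),
               nrow(gray), ncol(gray))
  structure(list(pixels = px, threshold = as.integer(thresh),
                 maxval = as.integer(maxval), source_id = source_id),
            class = "binarized_image")
}

#' Otsu-threshold and binarize in one step
#'
#' @inheritParams binarize
#' @export
binarize_otsu <- function(gray, maxval = 255L, source_id = NULL) {
  binarize(gray, otsu_threshold(gray), maxval, source_id)
}

#' @export
print.binarized_image <- function(x, ...) {
  cat(sprintf("<binarized_image> %dx%d, threshold %d, maxval %d\n",
              nrow(x$pixels), ncol(x$pixels), x$threshold, x$maxval))
  invisible(x)
}

#' Resize and scale a binarized image into network input form
#'
#' Nearest-neighbour resizing to `side x side` (preserving the two-valued
#' pixel set), then scaling `{0, maxval}` to `{0.0, 1.0}`.
#'
#' @param binary A `binarized_image` (or a `{0, maxval}` matrix plus
#'   `maxval`).
#' @param side Output side in pixels; a positive multiple of 8.
#' @param maxval High value used for scaling when `binary` is a plain
#'   matrix.
#' @return Numeric `side x side` matrix with values in `{0.0, 1.0}`.
#' @export
prepare_input <- function(binary, side = 128L, maxval = 255L) {
  if (length(side) != 1L || side <= 0 || side %% 8 != 0)
    stop("side must be a positive multiple of 8, got ", deparse(side))
  if (inherits(binary, "binarized_image")) {
    px <- binary$pixels
    maxval <- binary$maxval
  } else {
    px <- binary
  }
  h <- nrow(px); w <- ncol(px)
  ri <- pmin(h, floor((seq_len(side) - 0.5) * h / side) + 1L)
  ci <- pmin(w, floor((seq_len(side) - 0.5) * w / side) + 1L)
  px[ri, ci] / maxval
}

#' Read an 8-bit PNG as an integer image
#'
#' @param path PNG path.
#' @return Integer matrix (grayscale) or `H x W x 3` array (colour), 0-255.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3] == 4L) x <- x[, , 1:3]  # drop alpha
  y <- round(x * 255)
  if (length(dim(y)) == 2L) matrix(as.integer(y), nrow(y), ncol(y))
  else array(as.integer(y), dim(y))
}

#' Load a manifest's images as a prepared network input batch
#'
#' Reads each record's PNG, converts to grayscale, applies Otsu
#' binarization, and resizes to `side x side` network inputs.
#'
#' @param manifest A `dataset_manifest`.
#' @param side Network input side (multiple of 8).
#' @param maxval Binarization high value.
#' @return List with `x` (array `side x side x N x 1` of 0/1 values),
#'   `labels` (integer vector under the manifest scheme), `ids`.
#' @export
prepare_dataset <- function(manifest, side = 128L, maxval = 255L) {
  rec <- manifest$records
  n <- nrow(rec)
  x <- array(0, dim = c(side, side, n, 1L))
  for (i in seq_len(n)) {
    img <- read_image_png(file.path(manifest$dir, rec$path[i]))
    bw <- binarize_otsu(to_grayscale(img), maxval, source_id = rec$id[i])
    x[, , i, 1L] <- prepare_input(bw, side)
  }
  list(x = x, labels = manifest_labels(manifest), ids = rec$id)
}
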