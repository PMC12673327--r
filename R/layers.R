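#' @useDynLib kromnet, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

# Low-level differentiable layers.
#
# Internal feature-map layout is a 4-d array dim = c(H, W, N, C): spatial
# dims first (column-major R), then batch, then channels. Convolutions are
# im2col + GEMM; weights for a k x k conv are stored as a matrix with
# Cin*k*k rows (input channel fastest, then kernel offset) and Cout columns
# so the patch matrix multiplies directly.

# x: (H, W, N, Cin); Wm: (Cin*k*k, Cout); stride 1; zero padding chosen to
# preserve spatial size: p = dil * (k - 1) / 2 (k odd). Patch gather and
# gradient scatter run in C (src/conv_ops.cpp); the contraction is BLAS.
conv2d_forward <- function(x, Wm, b, k, dil = 1L, keep_cache = FALSE) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  stopifnot(nrow(Wm) == Cin * k * k, (k %% 2L) == 1L, dil >= 1L)
  p <- as.integer(dil * (k - 1L) / 2L)
  Xm <- im2col_nhwc(x, H, W, N, Cin, k, dil, p)
  Y <- Xm %*% Wm
  Y <- Y + rep(b, each = H * W * N)
  dim(Y) <- c(H, W, N, ncol(Wm))
  if (keep_cache) list(out = Y, Xm = Xm, dims = d, k = k, dil = dil, p = p)
  else list(out = Y)
}

conv2d_backward <- function(dY, cache, Wm) {
  d <- cache$dims
  H <- d[1]; W <- d[2]; N <- d[3]; Cin <- d[4]
  dYm <- matrix(dY, nrow = H * W * N)
  dWm <- crossprod(cache$Xm, dYm)
  db <- colSums(dYm)
  dP <- tcrossprod(dYm, Wm)   # (H*W*N, Cin*k*k)
  dx <- col2im_nhwc(dP, H, W, N, Cin, cache$k, cache$dil, cache$p)
  list(dx = dx, dW = dWm, db = db)
}

relu_forward <- function(x) { x[x < 0] <- 0; x }

# 2x2 max pooling, stride 2; window scan order (1,1),(2,1),(1,2),(2,2)
# with first-match tie-break (src/conv_ops.cpp).
maxpool2_forward <- function(x) {
  d <- dim(x)
  stopifnot(d[1] %% 2L == 0L, d[2] %% 2L == 0L)
  mp <- maxpool2_cpp(x, d[1], d[2], d[3], d[4])
  list(out = mp$out, which = mp$which, dims = d)
}

maxpool2_backward <- function(dout, cache) {
  d <- cache$dims
  maxpool2_bwd_cpp(dout, cache$which, d[1], d[2], d[3], d[4])
}

# batch global average pool: (H, W, N, C) -> (N, C)
gap_batch <- function(x) {
  d <- dim(x)
  matrix(colMeans(matrix(x, nrow = d[1] * d[2])), d[3], d[4])
}

# broadcast per-(sample, channel) scale s (N, C) over spatial dims
scale_channels <- function(x, s) {
  d <- dim(x)
  x * rep(as.vector(s), each = d[1] * d[2])
}

#' Global average pooling of a feature map
#'
#' Aggregates each channel's spatial extent into its arithmetic mean,
#' producing one descriptor per channel.
#'
#' @param M1 Numeric array `H x W x C` (a single feature map).
#' @return Numeric vector of length `C`.
#' @export
global_avg_pool <- function(M1) {
  d <- dim(M1)
  if (is.null(d) || length(d) != 3L || d[1] < 1L || d[2] < 1L)
    stop("expected an H x W x C array with nonempty spatial extent")
  as.vector(colMeans(matrix(M1, nrow = d[1] * d[2])))
}

#' Channel-attention weight computation
#'
#' Squeeze-style gating: the pooled channel descriptor passes through a
#' bottleneck linear map (`C -> C/r`), a ReLU, an expanding linear map
#' (`C/r -> C`), and a sigmoid, yielding per-channel weights strictly in
#' (0, 1).
#'
#' @param M2 Pooled channel descriptor, length `C`.
#' @param W1 `C x C/r` bottleneck weight matrix.
#' @param W2 `C/r x C` expansion weight matrix.
#' @param b1,b2 Bias vectors (default zero).
#' @return Weight vector `M3` of length `C`, entries in (0, 1).
#' @export
attention_weights <- function(M2, W1, W2, b1 = NULL, b2 = NULL) {
  C <- length(M2)
  if (nrow(W1) != C || ncol(W2) != C || ncol(W1) != nrow(W2))
    stop("attention weight shapes inconsistent with channel count ", C,
         " and the reduction ratio")
  if (is.null(b1)) b1 <- numeric(ncol(W1))
  if (is.null(b2)) b2 <- numeric(ncol(W2))
  z1 <- pmax(0, as.vector(M2 %*% W1) + b1)
  as.vector(1 / (1 + exp(-(as.vector(z1 %*% W2) + b2))))
}

#' Recalibrate a feature map with channel weights
#'
#' Multiplies each channel of `M1` by its attention weight (channel-by-
#' channel product).
#'
#' @param M1 Numeric array `H x W x C`.
#' @param M3 Weight vector of length `C`.
#' @return Array `H x W x C`.
#' @export
recalibrate <- function(M1, M3) {
  d <- dim(M1)
  if (length(M3) != d[3])
    stop("channel mismatch: feature map has ", d[3], " channels, weights ",
         length(M3))
  M1 * rep(M3, each = d[1] * d[2])
}

#' Dilated 2-d convolution (spatial-size preserving)
#'
#' Convolution with `rate - 1` implicit zeros between kernel taps, giving
#' an effective extent of `k + (k - 1)(rate - 1)` while zero padding keeps
#' the output spatial dims equal to the input's. Rate 1 recovers standard
#' convolution.
#'
#' @param input `H x W` matrix or `H x W x Cin` array.
#' @param kernel `k x k` matrix or `k x k x Cin x Cout` array, `k` odd.
#' @param rate Integer dilation rate `>= 1`.
#' @param bias Per-output-channel bias (default 0).
#' @return `H x W` matrix (single output channel) or `H x W x Cout` array.
#' @export
dilated_conv <- function(input, kernel, rate = 1L, bias = NULL) {
  if (rate < 1L || rate != as.integer(rate))
    stop("dilation rate must be an integer >= 1, got ", deparse(rate))
  if (is.matrix(input)) dim(input) <- c(dim(input), 1L)
  if (is.matrix(kernel)) dim(kernel) <- c(dim(kernel), 1L, 1L)
  dk <- dim(kernel)
  stopifnot(dk[1] == dk[2], dim(input)[3] == dk[3])
  k <- dk[1]; Cin <- dk[3]; Cout <- dk[4]
  if (is.null(bias)) bias <- numeric(Cout)
  # weight rows: input channel fastest, then offset (kx row-fastest, ky)
  Wm <- matrix(aperm(kernel, c(3L, 1L, 2L, 4L)), nrow = Cin * k * k)
  d <- dim(input)
  x <- array(input, dim = c(d[1], d[2], 1L, Cin))  # N = 1
  out <- conv2d_forward(x, Wm, bias, k, as.integer(rate))$out
  if (Cout == 1L) matrix(out, d[1], d[2]) else array(out, c(d[1], d[2], Cout))
}

# numerically stable row-wise softmax on an N x K matrix
softmax <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Bundle predicted probabilities with one-hot true labels
#'
#' @param probs `N x K` matrix of class probabilities; every row must sum
#'   to 1 within 1e-6 with entries in `[0, 1]`.
#' @param onehot `N x K` one-hot matrix of true labels (exactly one 1 per
#'   row), or an integer label vector in `[0, K-1]`.
#' @param ids Optional record ids.
#' @return Object of class `prediction_batch`.
#' @export
prediction_batch <- function(probs, onehot, ids = NULL) {
  probs <- as.matrix(probs)
  if (!is.matrix(onehot)) onehot <- onehot_encode(onehot, ncol(probs))
  if (!all(dim(probs) == dim(onehot)))
    stop("probs and onehot must have identical N x K dims")
  if (any(probs < -1e-9) || any(probs > 1 + 1e-9) ||
      any(abs(rowSums(probs) - 1) > 1e-6))
    stop("probability rows must lie in [0, 1] and sum to 1 within 1e-6")
  if (any(rowSums(onehot == 1) != 1L) || !all(onehot %in% c(0, 1)))
    stop("onehot rows must contain exactly one 1")
  structure(list(probs = probs, onehot = onehot, ids = ids),
            class = "prediction_batch")
}

#' One-hot encode integer labels
#' @param labels Integer labels in `[0, K-1]`.
#' @param K Number of classes.
#' @return `N x K` 0/1 matrix.
#' @export
onehot_encode <- function(labels, K) {
  if (any(labels < 0 | labels >= K))
    stop("labels must lie in [0, ", K - 1, "]")
  Y <- matrix(0, length(labels), K)
  Y[cbind(seq_along(labels), labels + 1L)] <- 1
  Y
}

#' Cross-entropy loss of a prediction batch
#'
#' The categorical cross-entropy between one-hot true labels and predicted
#' class probabilities, reported as the mean over the `N` samples (so the
#' learning rate is batch-size independent). Probabilities are clipped at
#' 1e-12 before the logarithm.
#'
#' @param batch A [prediction_batch()].
#' @return Nonnegative scalar; zero iff every sample puts probability 1 on
#'   its true class.
#' @export
cross_entropy <- function(batch) {
  stopifnot(inherits(batch, "prediction_batch"))
  p <- pmax(batch$probs, 1e-12)
  -sum(batch$onehot * log(p)) / nrow(p)
}
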