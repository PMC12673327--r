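# KROMNet: six convolutional layers, two dilated convolutional layers,
# two channel-attention layers and two fully connected layers, closed by a
# softmax head.

#' Describe a KROMNet architecture
#'
#' The layer counts are fixed by the architecture (6 conv blocks, 2 dilated
#' blocks, 2 attention positions, 2 fully connected layers); widths,
#' dilation rates and input side are configurable. Two presets are
#' provided: `"default"` (conv channels 16/32/32/64/64/128, dilated
#' 128 at rates 2 and 4, hidden 256) and `"small"`, a half-width variant
#' (8/16/16/32/32/64, dilated 64, hidden 128) used for desk-scale runs.
#'
#' @param num_classes K, 4 or 6.
#' @param input_side Input image side in pixels; must be divisible by 16
#'   (four 2x2 poolings).
#' @param preset `"default"` or `"small"`.
#' @param conv_channels Optional length-6 override of conv output channels.
#' @param dilated_channels Optional length-2 override.
#' @param dilation_rates Length-2 dilation rates (default 2, 4).
#' @param fc_hidden Hidden fully connected width.
#' @param reduction_ratio Attention bottleneck ratio (default 16); must
#'   divide every attended channel count.
#' @return Object of class `kromnet_spec`.
#' @export
kromnet_spec <- function(num_classes, input_side = 128L,
                         preset = c("default", "small"),
                         conv_channels = NULL, dilated_channels = NULL,
                         dilation_rates = c(2L, 4L), fc_hidden = NULL,
                         reduction_ratio = 16L) {
  preset <- match.arg(preset)
  if (!num_classes %in% c(4L, 6L))
    stop("num_classes must be 4 or 6, got ", num_classes)
  if (is.null(conv_channels))
    conv_channels <- if (preset == "default") c(16L, 32L, 32L, 64L, 64L, 128L)
                     else c(8L, 16L, 16L, 32L, 32L, 64L)
  if (is.null(dilated_channels))
    dilated_channels <- if (preset == "default") c(128L, 128L) else c(64L, 64L)
  if (is.null(fc_hidden)) fc_hidden <- if (preset == "default") 256L else 128L
  conv_channels <- as.integer(conv_channels)
  dilated_channels <- as.integer(dilated_channels)

  spec <- structure(list(
    conv_blocks = lapply(seq_len(length(conv_channels)), function(i) {
      list(out_channels = conv_channels[i], kernel = 3L, stride = 1L,
           pool = i %in% c(1L, 2L, 4L, 6L))
    }),
    dilated_blocks = lapply(seq_along(dilated_channels), function(i) {
      list(out_channels = dilated_channels[i], kernel = 3L,
           dilation = as.integer(dilation_rates[i]))
    }),
    attention_positions = c(1L, 2L),  # after each dilated block
    reduction_ratio = as.integer(reduction_ratio),
    fc_widths = c(as.integer(fc_hidden), as.integer(num_classes)),
    input_side = as.integer(input_side),
    num_classes = as.integer(num_classes)
  ), class = "kromnet_spec")
  validate_kromnet_spec(spec)
}

#' Validate a `kromnet_spec` against the architectural invariants
#' @param spec A `kromnet_spec`.
#' @return The spec, invisibly-checked (errors on violation).
#' @export
validate_kromnet_spec <- function(spec) {
  if (length(spec$conv_blocks) != 6L)
    stop("architecture requires exactly 6 convolutional blocks")
  if (length(spec$dilated_blocks) != 2L)
    stop("architecture requires exactly 2 dilated convolutional blocks")
  if (length(spec$attention_positions) != 2L)
    stop("architecture requires exactly 2 channel-attention layers")
  if (length(spec$fc_widths) != 2L)
    stop("architecture requires exactly 2 fully connected layers")
  rates <- vapply(spec$dilated_blocks, `[[`, integer(1), "dilation")
  if (any(rates < 1L)) stop("dilation rates must be >= 1")
  att_ch <- vapply(spec$dilated_blocks[spec$attention_positions],
                   `[[`, integer(1), "out_channels")
  if (any(att_ch %% spec$reduction_ratio != 0L))
    stop("reduction_ratio ", spec$reduction_ratio,
         " must divide every attended channel count (",
         paste(att_ch, collapse = ", "), ")")
  npool <- sum(vapply(spec$conv_blocks, `[[`, logical(1), "pool"))
  if (spec$input_side %% (2^npool) != 0L)
    stop("input_side must be divisible by ", 2^npool)
  spec
}

#' @export
print.kromnet_spec <- function(x, ...) {
  ch <- vapply(x$conv_blocks, `[[`, integer(1), "out_channels")
  dc <- vapply(x$dilated_blocks, `[[`, integer(1), "out_channels")
  dr <- vapply(x$dilated_blocks, `[[`, integer(1), "dilation")
  cat(sprintf(paste0("<kromnet_spec> K=%d, input %dx%d\n",
                     "  conv: %s (pool after 1,2,4,6)\n",
                     "  dilated: %s at rates %s; attention r=%d\n",
                     "  fc: %d -> %d\n"),
              x$num_classes, x$input_side, x$input_side,
              paste(ch, collapse = "-"), paste(dc, collapse = "-"),
              paste(dr, collapse = ","), x$reduction_ratio,
              x$fc_widths[1], x$fc_widths[2]))
  invisible(x)
}

.he_init <- function(nr, nc, fan_in) {
  matrix(stats::rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

#' Build a KROMNet model with seeded initialization
#'
#' Assembles the layer stack described by `spec` (conv+ReLU blocks with
#' 2x2 max pooling, dilation blocks, squeeze-style attention, FC head with
#' softmax) with He-initialized weights and zero biases. Two builds from
#' the same seed have identical initial parameters.
#'
#' @param spec A [kromnet_spec()].
#' @param seed Integer initialization seed.
#' @return Object of class `kromnet`.
#' @export
build_kromnet <- function(spec, seed = 1L) {
  validate_kromnet_spec(spec)
  layers <- list()
  withr::with_seed(as.integer(seed), {
    side <- spec$input_side
    cin <- 1L
    for (b in spec$conv_blocks) {
      k <- b$kernel; cout <- b$out_channels
      layers[[length(layers) + 1L]] <- list(
        type = "conv", k = k, dil = 1L, cin = cin, cout = cout,
        pool = b$pool,
        W = .he_init(cin * k * k, cout, cin * k * k), b = numeric(cout))
      cin <- cout
      if (b$pool) side <- side %/% 2L
    }
    for (i in seq_along(spec$dilated_blocks)) {
      b <- spec$dilated_blocks[[i]]
      k <- b$kernel; cout <- b$out_channels
      layers[[length(layers) + 1L]] <- list(
        type = "conv", k = k, dil = b$dilation, cin = cin, cout = cout,
        pool = FALSE,
        W = .he_init(cin * k * k, cout, cin * k * k), b = numeric(cout))
      cin <- cout
      if (i %in% spec$attention_positions) {
        r <- spec$reduction_ratio
        layers[[length(layers) + 1L]] <- list(
          type = "attn", C = cin, r = r,
          W1 = .he_init(cin, cin %/% r, cin), b1 = numeric(cin %/% r),
          W2 = .he_init(cin %/% r, cin, cin %/% r), b2 = numeric(cin))
      }
    }
    flat <- side * side * cin
    layers[[length(layers) + 1L]] <- list(
      type = "fc", relu = TRUE,
      W = .he_init(flat, spec$fc_widths[1], flat),
      b = numeric(spec$fc_widths[1]))
    layers[[length(layers) + 1L]] <- list(
      type = "fc", relu = FALSE,
      W = .he_init(spec$fc_widths[1], spec$fc_widths[2], spec$fc_widths[1]),
      b = numeric(spec$fc_widths[2]))
  })
  n_par <- sum(vapply(layers, function(l) {
    sum(vapply(l[names(l) %in% c("W", "b", "W1", "b1", "W2", "b2")],
               length, integer(1)))
  }, numeric(1)))
  structure(list(spec = spec, layers = layers, seed = as.integer(seed),
                 n_parameters = n_par),
            class = "kromnet")
}

#' @export
print.kromnet <- function(x, ...) {
  print(x$spec)
  cat(sprintf("  %d trainable parameters, init seed %d\n",
              x$n_parameters, x$seed))
  invisible(x)
}

# Forward pass. x: (side, side, N, 1). Returns probs (N, K) and, if
# requested, the per-layer caches needed for backward / attention export.
kromnet_forward <- function(model, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$layers)) else NULL
  h <- x
  for (i in seq_along(model$layers)) {
    l <- model$layers[[i]]
    if (l$type == "conv") {
      cv <- conv2d_forward(h, l$W, l$b, l$k, l$dil, keep_cache = keep_cache)
      pre <- cv$out
      h <- relu_forward(pre)
      pl <- NULL
      if (l$pool) {
        pl <- maxpool2_forward(h)
        h <- pl$out
      }
      if (keep_cache) caches[[i]] <- list(conv = cv, pre = pre, pool = pl)
    } else if (l$type == "attn") {
      M2 <- gap_batch(h)                                   # (N, C)
      Z1 <- M2 %*% l$W1 + rep(l$b1, each = nrow(M2))
      A1 <- relu_forward(Z1)
      Z2 <- A1 %*% l$W2 + rep(l$b2, each = nrow(A1))
      M3 <- 1 / (1 + exp(-Z2))
      out <- scale_channels(h, M3)
      if (keep_cache)
        caches[[i]] <- list(input = h, M2 = M2, Z1 = Z1, A1 = A1, M3 = M3)
      h <- out
    } else {  # fc
      if (!is.matrix(h)) {
        d <- dim(h)
        h <- matrix(aperm(h, c(3L, 1L, 2L, 4L)), nrow = d[3])
      }
      pre <- h %*% l$W + rep(l$b, each = nrow(h))
      if (keep_cache) caches[[i]] <- list(input = h, pre = pre)
      h <- if (l$relu) relu_forward(pre) else pre
    }
  }
  list(probs = softmax(h), logits = h, caches = caches)
}

# Backward pass from softmax + mean cross-entropy. Returns grads aligned
# with model$layers.
kromnet_backward <- function(model, fwd, onehot) {
  N <- nrow(onehot)
  grads <- vector("list", length(model$layers))
  dh <- (fwd$probs - onehot) / N          # d(mean CE)/d(logits)
  for (i in rev(seq_along(model$layers))) {
    l <- model$layers[[i]]
    cache <- fwd$caches[[i]]
    if (l$type == "fc") {
      if (l$relu) dh <- dh * (cache$pre > 0)
      grads[[i]] <- list(W = crossprod(cache$input, dh), b = colSums(dh))
      dh <- tcrossprod(dh, l$W)
    } else if (l$type == "attn") {
      hin <- cache$input
      d <- dim(hin)
      HW <- d[1] * d[2]
      if (is.matrix(dh)) {  # arrived from fc flatten: rows = samples
        dh <- array(aperm(array(dh, c(d[3], d[1], d[2], d[4])),
                          c(2L, 3L, 1L, 4L)), d)
      }
      dM3 <- matrix(colSums(matrix(dh * hin, nrow = HW)), d[3], d[4])
      dx <- scale_channels(dh, cache$M3)
      dZ2 <- dM3 * cache$M3 * (1 - cache$M3)
      dW2 <- crossprod(cache$A1, dZ2); db2 <- colSums(dZ2)
      dA1 <- tcrossprod(dZ2, l$W2)
      dZ1 <- dA1 * (cache$Z1 > 0)
      dW1 <- crossprod(cache$M2, dZ1); db1 <- colSums(dZ1)
      dM2 <- tcrossprod(dZ1, l$W1)
      dx <- dx + rep(as.vector(dM2), each = HW) / HW
      grads[[i]] <- list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2)
      dh <- dx
    } else {  # conv
      if (is.matrix(dh)) {  # arrived from fc flatten
        dims_out <- if (!is.null(cache$pool)) dim(cache$pool$out)
                    else dim(cache$pre)
        dh <- array(aperm(array(dh, c(dims_out[3], dims_out[1],
                                      dims_out[2], dims_out[4])),
                          c(2L, 3L, 1L, 4L)), dims_out)
      }
      if (!is.null(cache$pool)) dh <- maxpool2_backward(dh, cache$pool)
      dh <- dh * (cache$pre > 0)
      bk <- conv2d_backward(dh, cache$conv, l$W)
      grads[[i]] <- list(W = bk$dW, b = bk$db)
      dh <- bk$dx
    }
  }
  grads
}

#' Predict class probabilities for prepared inputs
#'
#' @param object A `kromnet` model.
#' @param x Prepared input array `side x side x N x 1` (see
#'   [prepare_input()]), or a single `side x side` matrix.
#' @param chunk Number of images processed per forward pass.
#' @param ... Unused.
#' @return `N x K` matrix of class probabilities (rows sum to 1).
#' @export
predict.kromnet <- function(object, x, chunk = 64L, ...) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  n <- dim(x)[3]
  K <- object$spec$num_classes
  probs <- matrix(0, n, K)
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    probs[idx, ] <- kromnet_forward(object,
                                    x[, , idx, , drop = FALSE])$probs
  }
  probs
}

# ---- Adam -------------------------------------------------------------

.param_names <- function(l)
  intersect(c("W", "b", "W1", "b1", "W2", "b2"), names(l))

adam_init <- function(model) {
  list(t = 0L, m = lapply(model$layers, function(l) {
    lapply(l[.param_names(l)], function(p) array(0, dim = dim(p) %||% length(p)))
  }), v = lapply(model$layers, function(l) {
    lapply(l[.param_names(l)], function(p) array(0, dim = dim(p) %||% length(p)))
  }))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

adam_step <- function(model, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(model$layers)) {
    for (p in .param_names(model$layers[[i]])) {
      g <- grads[[i]][[p]]
      state$m[[i]][[p]] <- beta1 * state$m[[i]][[p]] + (1 - beta1) * g
      state$v[[i]][[p]] <- beta2 * state$v[[i]][[p]] + (1 - beta2) * g * g
      mhat <- state$m[[i]][[p]] / bc1
      vhat <- state$v[[i]][[p]] / bc2
      old <- model$layers[[i]][[p]]
      upd <- old - lr * mhat / (sqrt(vhat) + eps)
      dim(upd) <- dim(old)
      model$layers[[i]][[p]] <- upd
    }
  }
  list(model = model, state = state)
}

sgd_step <- function(model, grads, lr) {
  for (i in seq_along(model$layers)) {
    for (p in .param_names(model$layers[[i]])) {
      model$layers[[i]][[p]] <- model$layers[[i]][[p]] - lr * grads[[i]][[p]]
    }
  }
  model
}

#' Save / load a KROMNet model
#'
#' The model (layer parameters plus embedded spec) is serialized with R's
#' native RDS format; reloading reproduces predictions exactly.
#'
#' @param model A `kromnet`.
#' @param path File path.
#' @return `save_kromnet` the path, `load_kromnet` the model.
#' @export
save_kromnet <- function(model, path) {
  stopifnot(inherits(model, "kromnet"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_kromnet
#' @export
load_kromnet <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "kromnet"))
  model
}

#' Serialize / restore a network spec as YAML
#'
#' @param spec A [kromnet_spec()].
#' @param path YAML file path.
#' @return `write_kromnet_spec` the path; `read_kromnet_spec` the spec.
#' @export
write_kromnet_spec <- function(spec, path) {
  validate_kromnet_spec(spec)
  yaml::write_yaml(unclass(spec), path)
  invisible(path)
}

#' @rdname write_kromnet_spec
#' @export
read_kromnet_spec <- function(path) {
  raw <- yaml::read_yaml(path)
  raw$conv_blocks <- lapply(raw$conv_blocks, function(b) {
    b[c("out_channels", "kernel", "stride")] <-
      lapply(b[c("out_channels", "kernel", "stride")], as.integer)
    b
  })
  raw$dilated_blocks <- lapply(raw$dilated_blocks, function(b) {
    lapply(b, as.integer)
  })
  for (f in c("attention_positions", "reduction_ratio", "fc_widths",
              "input_side", "num_classes"))
    raw[[f]] <- as.integer(raw[[f]])
  validate_kromnet_spec(structure(raw, class = "kromnet_spec"))
}
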