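# Independent brute-force oracles used by the tests. These deliberately
# avoid the package's own vectorized implementations.

# Otsu: exhaustive scan of all 256 thresholds, computing the two class
# populations directly from the pixel vector.
oracle_otsu <- function(v) {
  v <- as.integer(v)
  n <- length(v)
  best_t <- 0L
  best_var <- -1
  for (t in 0:255) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) {
      s <- 0
    } else {
      w0 <- length(lo) / n
      w1 <- length(hi) / n
      s <- w0 * w1 * (mean(lo) - mean(hi))^2
    }
    if (s > best_var + 1e-12) {
      best_var <- s
      best_t <- t
    }
  }
  best_t
}

# Direct quadruple-loop 2-d convolution with dilation and zero padding
# preserving spatial size (stride 1, odd kernel).
oracle_conv2d <- function(x, kernel, rate = 1L) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  if (is.matrix(kernel)) dim(kernel) <- c(dim(kernel), 1L, 1L)
  H <- dim(x)[1]; W <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(kernel)[1]; Cout <- dim(kernel)[4]
  p <- rate * (k - 1L) / 2L
  out <- array(0, c(H, W, Cout))
  for (co in seq_len(Cout)) for (i in seq_len(H)) for (j in seq_len(W)) {
    acc <- 0
    for (ci in seq_len(Cin)) for (a in seq_len(k)) for (b in seq_len(k)) {
      ii <- i + (a - 1L) * rate - p
      jj <- j + (b - 1L) * rate - p
      if (ii >= 1L && ii <= H && jj >= 1L && jj <= W)
        acc <- acc + x[ii, jj, ci] * kernel[a, b, ci, co]
    }
    out[i, j, co] <- acc
  }
  if (Cout == 1L) matrix(out, H, W) else out
}

# Scalar double loop over Eq.-style spatial mean per channel.
oracle_gap <- function(M1) {
  d <- dim(M1)
  out <- numeric(d[3])
  for (c in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) s <- s + M1[i, j, c]
    out[c] <- s / (d[1] * d[2])
  }
  out
}

# Explicit N x K double sum of the cross-entropy, reported per sample.
oracle_cross_entropy <- function(probs, onehot) {
  total <- 0
  for (i in seq_len(nrow(probs))) for (c in seq_len(ncol(probs)))
    total <- total - onehot[i, c] * log(max(probs[i, c], 1e-12))
  total / nrow(probs)
}

# Counting oracle for the classification metrics: works from raw label
# vectors with per-class tallies, no matrix algebra.
oracle_metrics <- function(pred, true, K) {
  per <- data.frame(precision = numeric(K), recall = numeric(K),
                    f1 = numeric(K))
  for (k in 0:(K - 1L)) {
    tp <- sum(pred == k & true == k)
    fp <- sum(pred == k & true != k)
    fn <- sum(pred != k & true == k)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    per$precision[k + 1] <- p
    per$recall[k + 1] <- r
    per$f1[k + 1] <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  }
  list(per_class = per,
       precision = mean(per$precision), recall = mean(per$recall),
       f1 = mean(per$f1), accuracy = 100 * sum(pred == true) / length(true))
}

# Finite-difference gradient check on a tiny network; returns the worst
# scaled discrepancy over sampled parameters.
gradcheck_worst <- function(model, x, onehot, n_per_param = 5L, eps = 1e-5) {
  kf <- kromnet:::kromnet_forward
  kb <- kromnet:::kromnet_backward
  lossfn <- function(m) {
    p <- pmax(kf(m, x)$probs, 1e-12)
    -sum(onehot * log(p)) / nrow(onehot)
  }
  fwd <- kf(model, x, keep_cache = TRUE)
  gr <- kb(model, fwd, onehot)
  worst <- 0
  for (i in seq_along(model$layers)) {
    for (pn in names(gr[[i]])) {
      P <- model$layers[[i]][[pn]]
      for (j in sample(length(P), min(n_per_param, length(P)))) {
        m2 <- model
        m2$layers[[i]][[pn]][j] <- P[j] + eps
        lp <- lossfn(m2)
        m2$layers[[i]][[pn]][j] <- P[j] - eps
        lm <- lossfn(m2)
        num <- (lp - lm) / (2 * eps)
        ana <- gr[[i]][[pn]][j]
        worst <- max(worst, abs(num - ana) / max(1e-4, abs(num) + abs(ana)))
      }
    }
  }
  worst
}
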