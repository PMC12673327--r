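#' Build a confusion matrix from label vectors
#'
#' `counts[i, j]` is the number of records with true class `i` and
#' predicted class `j` (0-based classes on both axes). Per-class TP, FP,
#' FN and TN follow the one-vs-rest reading: TP is the diagonal entry, FP
#' the remainder of the predicted column, FN the remainder of the true
#' row, and TN everything else.
#'
#' @param pred_labels,true_labels Equal-length integer vectors in
#'   `[0, K-1]`.
#' @param K Number of classes.
#' @return Object of class `confusion_matrix` with `counts` (K x K),
#'   `tp`, `fp`, `fn`, `tn`, `total`.
#' @export
confusion <- function(pred_labels, true_labels, K) {
  if (length(pred_labels) != length(true_labels))
    stop("label vectors must have equal length")
  if (any(pred_labels < 0 | pred_labels >= K |
          true_labels < 0 | true_labels >= K))
    stop("labels must lie in [0, ", K - 1L, "]")
  lev <- 0:(K - 1L)
  counts <- as.matrix(table(factor(true_labels, levels = lev),
                            factor(pred_labels, levels = lev)))
  dimnames(counts) <- list(true = lev, predicted = lev)
  tp <- diag(counts)
  fp <- colSums(counts) - tp
  fn <- rowSums(counts) - tp
  total <- sum(counts)
  structure(list(counts = counts, tp = tp, fp = fp, fn = fn,
                 tn = total - tp - fp - fn, total = total),
            class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> %d classes, %d records\n",
              nrow(x$counts), x$total))
  print(x$counts)
  invisible(x)
}

.safe_div <- function(num, den, what) {
  bad <- den == 0
  if (any(bad))
    warning("zero denominator in per-class ", what,
            " for class(es) ", paste(which(bad) - 1L, collapse = ", "),
            "; recording 0", call. = FALSE)
  ifelse(bad, 0, num / den)
}

#' Precision, recall, F1 and accuracy from a confusion matrix
#'
#' Per-class precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and their
#' harmonic-mean F1 are macro-averaged over classes (equal class weight);
#' classes with an empty denominator contribute 0 with a warning.
#' Accuracy is the micro quantity `trace/total x 100` (percent). Micro and
#' support-weighted precision/recall/F1 variants are also reported.
#'
#' @param cm A [confusion()] matrix.
#' @return Object of class `metrics_report`: `per_class` data frame,
#'   macro `precision`, `recall`, `f1`, `accuracy` (percent), plus
#'   `micro` and `weighted` lists.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  if (cm$total == 0) stop("empty confusion matrix")
  prec <- .safe_div(cm$tp, cm$tp + cm$fp, "precision")
  rec <- .safe_div(cm$tp, cm$tp + cm$fn, "recall")
  f1 <- ifelse(prec + rec == 0, 0, 2 * prec * rec / (prec + rec))
  support <- rowSums(cm$counts)
  per_class <- data.frame(class = seq_len(nrow(cm$counts)) - 1L,
                          precision = unname(prec), recall = unname(rec),
                          f1 = unname(f1), support = unname(support))
  tp_all <- sum(cm$tp)
  micro_p <- tp_all / sum(cm$tp + cm$fp)
  micro_r <- tp_all / sum(cm$tp + cm$fn)
  w <- support / cm$total
  structure(list(
    per_class = per_class,
    precision = mean(prec), recall = mean(rec), f1 = mean(f1),
    accuracy = 100 * tp_all / cm$total,
    micro = list(precision = micro_p, recall = micro_r,
                 f1 = 2 * micro_p * micro_r / (micro_p + micro_r)),
    weighted = list(precision = sum(w * prec), recall = sum(w * rec),
                    f1 = sum(w * f1))
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("<metrics_report> macro P %.4f  R %.4f  F1 %.4f  ",
                     "accuracy %.2f%%\n"),
              x$precision, x$recall, x$f1, x$accuracy))
  invisible(x)
}

#' Export channel-attention maps for one image
#'
#' Runs a forward pass and, for each attention layer, returns the
#' per-channel weight vector (`M3`, sigmoid outputs strictly in (0, 1))
#' and a spatial overlay: the weight-scaled channel mean of the
#' recalibrated feature map, min-max normalized to `[0, 1]` and upsampled
#' (nearest-neighbour) to the network input resolution. Optionally writes
#' each overlay as a grayscale heatmap PNG.
#'
#' @param model A `kromnet` containing attention layers.
#' @param image Prepared `side x side` input matrix (see
#'   [prepare_input()]).
#' @param out_dir If non-`NULL`, overlays are written there as
#'   `attention_layer<i>.png`.
#' @return List with one element per attention layer: `weights` (length-C
#'   vector) and `overlay` (`side x side` matrix in `[0, 1]`).
#' @export
export_attention_maps <- function(model, image, out_dir = NULL) {
  att_idx <- which(vapply(model$layers, function(l) l$type == "attn",
                          logical(1)))
  if (length(att_idx) == 0L) stop("model has no attention layers")
  x <- image
  dim(x) <- c(dim(image), 1L, 1L)
  fwd <- kromnet_forward(model, x, keep_cache = TRUE)
  side <- model$spec$input_side
  out <- lapply(seq_along(att_idx), function(j) {
    i <- att_idx[j]
    cache <- fwd$caches[[i]]
    w <- as.vector(cache$M3)
    m4 <- scale_channels(cache$input, cache$M3)
    d <- dim(m4)
    overlay <- matrix(rowMeans(matrix(m4, nrow = d[1] * d[2])), d[1], d[2])
    rng <- range(overlay)
    overlay <- if (diff(rng) > 0) (overlay - rng[1]) / diff(rng)
               else matrix(0, d[1], d[2])
    ri <- pmin(d[1], floor((seq_len(side) - 0.5) * d[1] / side) + 1L)
    overlay <- overlay[ri, ri]
    if (!is.null(out_dir)) {
      dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
      png::writePNG(overlay,
                    file.path(out_dir, sprintf("attention_layer%d.png", j)))
    }
    list(weights = w, overlay = overlay)
  })
  names(out) <- sprintf("attention%d", seq_along(att_idx))
  out
}

.heatmap_png <- function(counts, path, scale = 32L) {
  ramp <- grDevices::colorRamp(c("#440154", "#31688e", "#35b779", "#fde725"))
  v <- counts / max(1, max(counts))
  rgb <- ramp(as.vector(v)) / 255
  K <- nrow(counts)
  img <- array(0, dim = c(K, K, 3))
  for (ch in 1:3) img[, , ch] <- matrix(rgb[, ch], K, K)
  big <- array(0, dim = c(K * scale, K * scale, 3))
  idx <- rep(seq_len(K), each = scale)
  for (ch in 1:3) big[, , ch] <- img[idx, idx, ch]
  png::writePNG(big, path)
  invisible(path)
}

#' Write a metrics report and confusion matrix to disk
#'
#' Emits `metrics.csv` (per-class rows plus macro/micro/weighted rows with
#' 4-decimal fractions, and an `accuracy_percent` row with 2 decimals),
#' `confusion.csv`, and a `confusion.png` heatmap. Output is byte-stable
#' across reruns on identical inputs.
#'
#' @param report A [compute_metrics()] report.
#' @param cm The corresponding [confusion()] matrix.
#' @param out_dir Output directory (created if needed).
#' @return The output directory, invisibly.
#' @export
write_report <- function(report, cm, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("unwritable output path: ", out_dir)
  f4 <- function(x) sprintf("%.4f", x)
  pc <- report$per_class
  lines <- c("class,precision,recall,f1,support",
             sprintf("%d,%s,%s,%s,%d", pc$class, f4(pc$precision),
                     f4(pc$recall), f4(pc$f1), pc$support),
             sprintf("macro,%s,%s,%s,%d", f4(report$precision),
                     f4(report$recall), f4(report$f1), cm$total),
             sprintf("micro,%s,%s,%s,%d", f4(report$micro$precision),
                     f4(report$micro$recall), f4(report$micro$f1), cm$total),
             sprintf("weighted,%s,%s,%s,%d", f4(report$weighted$precision),
                     f4(report$weighted$recall), f4(report$weighted$f1),
                     cm$total),
             sprintf("accuracy_percent,%.2f,,,", report$accuracy))
  writeLines(lines, file.path(out_dir, "metrics.csv"))
  utils::write.csv(cm$counts, file.path(out_dir, "confusion.csv"))
  .heatmap_png(cm$counts, file.path(out_dir, "confusion.png"))
  invisible(out_dir)
}
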