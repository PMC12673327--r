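#' Training protocol configuration
#'
#' Defaults follow the study protocol: batch size 16, learning rate
#' 0.0002, 100 epochs, 8:2 train/test split. The optimizer is Adam
#' (beta1 = 0.9, beta2 = 0.999); plain SGD is available by name.
#' Stratified splitting (per-class 8:2) is on by default so the test set
#' preserves the class composition.
#'
#' @param batch_size Mini-batch size (>= 1).
#' @param learning_rate Positive step size.
#' @param epochs Maximum number of epochs.
#' @param split_ratio Train fraction in (0, 1).
#' @param optimizer `"adam"` or `"sgd"`.
#' @param seed Integer seed controlling splitting, initialization-free
#'   shuffling and any other training randomness.
#' @param stratified Per-class splitting flag.
#' @return Object of class `training_config`.
#' @export
training_config <- function(batch_size = 16L, learning_rate = 2e-4,
                            epochs = 100L, split_ratio = 0.8,
                            optimizer = c("adam", "sgd"), seed = 1L,
                            stratified = TRUE) {
  optimizer <- match.arg(optimizer)
  if (split_ratio <= 0 || split_ratio >= 1)
    stop("split_ratio must lie in (0, 1)")
  if (batch_size < 1L) stop("batch_size must be >= 1")
  if (learning_rate < 0) stop("learning_rate must be nonnegative")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 split_ratio = split_ratio, optimizer = optimizer,
                 seed = as.integer(seed), stratified = stratified),
            class = "training_config")
}

#' Split a dataset manifest into train and test sets
#'
#' Deterministic, seeded 8:2 (by default) partition. Under stratification
#' each class contributes `floor(split_ratio * n_class)` records to the
#' training set; otherwise `floor(split_ratio * N)` records are drawn
#' globally. The assignment is recorded in the manifest's `split` column.
#'
#' @param manifest A `dataset_manifest`.
#' @param config A [training_config()].
#' @return List with `train` and `test` manifests plus the full `manifest`
#'   carrying the filled `split` column.
#' @export
split_dataset <- function(manifest, config = training_config()) {
  rec <- manifest$records
  n <- nrow(rec)
  K <- .n_classes(manifest$scheme)
  if (n < K) stop("need at least ", K, " records to split")
  labels <- manifest_labels(manifest)
  split <- rep("test", n)
  withr::with_seed(config$seed, {
    if (config$stratified) {
      for (k in 0:(K - 1L)) {
        idx <- which(labels == k)
        if (length(idx) == 0L)
          stop("class ", k, " has zero records; cannot stratify")
        ntr <- floor(config$split_ratio * length(idx))
        split[sample(idx, ntr)] <- "train"
      }
    } else {
      ntr <- floor(config$split_ratio * n)
      split[sample.int(n, ntr)] <- "train"
    }
  })
  rec$split <- split
  sub <- function(keep) {
    m <- manifest
    m$records <- rec[rec$split == keep, , drop = FALSE]
    lab <- if (m$scheme == "four_class") m$records$label4 else m$records$label6
    m$class_counts <- as.integer(tabulate(lab + 1L, K))
    m
  }
  full <- manifest
  full$records <- rec
  list(train = sub("train"), test = sub("test"), manifest = full)
}

#' Train a KROMNet model
#'
#' Minimizes the mean cross-entropy objective by seeded mini-batch
#' gradient descent with the configured optimizer. Shuffling is reseeded
#' deterministically from `config$seed`, so two runs with the same seed
#' and data are identical. Training aborts with a diagnostic if the loss
#' becomes non-finite.
#'
#' @param model A `kromnet` built with [build_kromnet()]; its class count
#'   must match the labels.
#' @param x Prepared inputs, array `side x side x N x 1`.
#' @param labels Integer labels in `[0, K-1]`.
#' @param config A [training_config()].
#' @param x_test,test_labels Optional held-out data evaluated after each
#'   epoch.
#' @param verbose Print per-epoch progress.
#' @return List with `model` (trained) and `history` (data frame
#'   `epoch,train_loss,train_acc,test_acc`; train accuracy is the running
#'   estimate over that epoch's pre-update batches).
#' @export
train_kromnet <- function(model, x, labels, config = training_config(),
                          x_test = NULL, test_labels = NULL,
                          verbose = FALSE) {
  n <- dim(x)[3]
  if (n == 0L) stop("training data is empty")
  K <- model$spec$num_classes
  if (any(labels < 0 | labels >= K))
    stop("label outside [0, ", K - 1L, "] found")
  Y <- onehot_encode(labels, K)
  state <- if (config$optimizer == "adam") adam_init(model) else NULL
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), test_acc = numeric(0))

  withr::with_seed(config$seed, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      loss_sum <- 0; correct <- 0L
      for (s in seq(1L, n, by = config$batch_size)) {
        idx <- ord[s:min(n, s + config$batch_size - 1L)]
        xb <- x[, , idx, , drop = FALSE]
        yb <- Y[idx, , drop = FALSE]
        fwd <- kromnet_forward(model, xb, keep_cache = TRUE)
        p <- pmax(fwd$probs, 1e-12)
        loss <- -sum(yb * log(p)) / length(idx)
        if (!is.finite(loss))
          stop("non-finite loss at epoch ", epoch,
               " (batch starting at ", s, "); aborting")
        loss_sum <- loss_sum + loss * length(idx)
        correct <- correct +
          sum(max.col(fwd$probs, ties.method = "first") ==
              max.col(yb, ties.method = "first"))
        grads <- kromnet_backward(model, fwd, yb)
        if (config$optimizer == "adam") {
          st <- adam_step(model, grads, state, config$learning_rate)
          model <- st$model; state <- st$state
        } else {
          model <- sgd_step(model, grads, config$learning_rate)
        }
      }
      test_acc <- NA_real_
      if (!is.null(x_test)) {
        pr <- predict(model, x_test)
        test_acc <- mean(max.col(pr, ties.method = "first") - 1L ==
                         test_labels)
      }
      hist <- rbind(hist, data.frame(epoch = epoch,
                                     train_loss = loss_sum / n,
                                     train_acc = correct / n,
                                     test_acc = test_acc))
      if (verbose)
        message(sprintf("epoch %3d  loss %.6f  acc %.4f  test %.4f",
                        epoch, loss_sum / n, correct / n, test_acc))
    }
  })
  list(model = model, history = hist)
}

#' Accuracy of model predictions on prepared data
#' @param model A `kromnet`.
#' @param x Prepared inputs.
#' @param labels Integer labels in `[0, K-1]`.
#' @return List with `pred` (integer labels) and `accuracy` (fraction).
#' @export
evaluate_kromnet <- function(model, x, labels) {
  pr <- predict(model, x)
  pred <- max.col(pr, ties.method = "first") - 1L
  list(pred = pred, accuracy = mean(pred == labels), probs = pr)
}
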