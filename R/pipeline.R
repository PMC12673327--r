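# End-to-end pipeline: generate -> binarize -> train -> evaluate, driven
# by a nested configuration that mirrors the module structure.

#' Default pipeline configuration
#'
#' Nested sections mirror the pipeline stages. `synthgen$class_counts`
#' defaults to the study composition (four-class 300/243/272/288,
#' six-class 139/206/219/221/204/165); `schemes` selects which task(s) to
#' run.
#'
#' @return Nested list of class `pipeline_config`.
#' @export
default_pipeline_config <- function() {
  structure(list(
    global_seed = 1L,
    output_root = "runs",
    run_name = "run",
    schemes = "four_class",
    synthgen = list(
      class_counts = list(four_class = c(300L, 243L, 272L, 288L),
                          six_class = c(139L, 206L, 219L, 221L, 204L, 165L)),
      canvas = 128L,
      clean = FALSE),
    imaging = list(maxval = 255L, input_side = 128L),
    network = list(preset = "default"),
    training = list(batch_size = 16L, learning_rate = 2e-4, epochs = 100L,
                    split_ratio = 0.8, optimizer = "adam",
                    stratified = TRUE),
    evaluation = list(export_attention = TRUE)
  ), class = "pipeline_config")
}

.check_config_keys <- function(cfg, ref, path = "") {
  unknown <- setdiff(names(cfg), names(ref))
  if (length(unknown) > 0L)
    stop("unknown configuration key: ", path, unknown[1], call. = FALSE)
  for (k in names(cfg)) {
    if (is.list(ref[[k]]) && !is.null(names(ref[[k]]))) {
      if (!is.list(cfg[[k]]))
        stop("configuration section ", path, k, " must be a mapping",
             call. = FALSE)
      .check_config_keys(cfg[[k]], ref[[k]], paste0(path, k, "$"))
    }
  }
}

.merge_config <- function(base, override) {
  for (k in names(override)) {
    if (is.list(base[[k]]) && is.list(override[[k]]) &&
        !is.null(names(base[[k]]))) {
      base[[k]] <- .merge_config(base[[k]], override[[k]])
    } else {
      base[[k]] <- override[[k]]
    }
  }
  base
}

#' Read and validate a pipeline configuration
#'
#' Loads a YAML file, rejects unknown keys (naming the first offender),
#' and merges it over [default_pipeline_config()].
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @param overrides Optional named list merged last (e.g. from CLI flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path = NULL, overrides = NULL) {
  cfg <- default_pipeline_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    .check_config_keys(user, cfg)
    cfg <- .merge_config(cfg, user)
  }
  if (!is.null(overrides)) {
    .check_config_keys(overrides, cfg)
    cfg <- .merge_config(cfg, overrides)
  }
  class(cfg) <- "pipeline_config"
  cfg
}

.log_line <- function(log_path, ...) {
  msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
  message(msg)
  cat(msg, "\n", file = log_path, append = TRUE)
}

#' Run the full pipeline on synthetic data
#'
#' Generates a labelled synthetic dataset, Otsu-binarizes and resizes it,
#' trains a model per requested scheme, and writes metrics, confusion
#' matrices, attention maps, training history, logs and the fully resolved
#' configuration into a self-describing run directory.
#'
#' @param config A `pipeline_config` (see [read_pipeline_config()]).
#' @return The run directory path, invisibly. Errors from any stage
#'   propagate with the stage name prefixed.
#' @export
run_end_to_end <- function(config = default_pipeline_config()) {
  .check_config_keys(unclass(config), default_pipeline_config())
  run_dir <- file.path(config$output_root, config$run_name)
  dir.create(run_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(run_dir, "run.log")
  cat("", file = log_path)
  yaml::write_yaml(unclass(config), file.path(run_dir, "config.yaml"))
  .log_line(log_path, "run directory: ", run_dir,
            " (global seed ", config$global_seed, ")")

  stage <- function(name, expr) {
    tryCatch({
      t0 <- Sys.time()
      out <- force(expr)
      .log_line(log_path, name, " done in ",
                sprintf("%.1f", as.numeric(Sys.time() - t0, units = "secs")),
                " s")
      out
    }, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  for (scheme in config$schemes) {
    .check_scheme(scheme)
    sdir <- file.path(run_dir, scheme)
    counts <- config$synthgen$class_counts[[scheme]]
    manifest <- stage(paste0(scheme, "/generate"),
      generate_dataset(scheme, counts, file.path(sdir, "data"),
                       global_seed = config$global_seed,
                       canvas = config$synthgen$canvas,
                       clean = isTRUE(config$synthgen$clean)))

    tcfg <- training_config(
      batch_size = config$training$batch_size,
      learning_rate = config$training$learning_rate,
      epochs = config$training$epochs,
      split_ratio = config$training$split_ratio,
      optimizer = config$training$optimizer,
      seed = config$global_seed + 1L,
      stratified = isTRUE(config$training$stratified))

    sp <- stage(paste0(scheme, "/split"), split_dataset(manifest, tcfg))
    write_manifest(sp$manifest, file.path(sdir, "data", "manifest.csv"))

    side <- config$imaging$input_side
    tr <- stage(paste0(scheme, "/preprocess-train"),
                prepare_dataset(sp$train, side, config$imaging$maxval))
    te <- stage(paste0(scheme, "/preprocess-test"),
                prepare_dataset(sp$test, side, config$imaging$maxval))

    spec <- kromnet_spec(.n_classes(scheme), input_side = side,
                         preset = config$network$preset)
    model <- build_kromnet(spec, seed = config$global_seed + 2L)
    .log_line(log_path, scheme, ": model with ", model$n_parameters,
              " parameters")
    fit <- stage(paste0(scheme, "/train"),
                 train_kromnet(model, tr$x, tr$labels, tcfg,
                               x_test = te$x, test_labels = te$labels))
    utils::write.csv(
      data.frame(epoch = fit$history$epoch,
                 train_loss = sprintf("%.6f", fit$history$train_loss),
                 train_acc = sprintf("%.6f", fit$history$train_acc),
                 test_acc = sprintf("%.6f", fit$history$test_acc)),
      file.path(sdir, "history.csv"), row.names = FALSE, quote = FALSE)

    ev <- stage(paste0(scheme, "/evaluate"), {
      res <- evaluate_kromnet(fit$model, te$x, te$labels)
      cm <- confusion(res$pred, te$labels, .n_classes(scheme))
      rep <- compute_metrics(cm)
      write_report(rep, cm, file.path(sdir, "report"))
      list(cm = cm, report = rep)
    })
    .log_line(log_path, scheme, ": test accuracy ",
              sprintf("%.2f%%", ev$report$accuracy),
              ", macro F1 ", sprintf("%.4f", ev$report$f1))

    save_kromnet(fit$model, file.path(sdir, "model.rds"))
    if (isTRUE(config$evaluation$export_attention)) {
      stage(paste0(scheme, "/attention"),
            export_attention_maps(fit$model, te$x[, , 1L, 1L],
                                  file.path(sdir, "attention")))
    }
  }
  invisible(run_dir)
}

#' Write the deterministic fixture sets used by the test suite
#'
#' Produces three fixtures under `out`:
#' * `overfit16/` -- a 16-image four-class set (4 per label), noiseless;
#' * `clean64/` -- a 64-image four-class noiseless set (16 per label);
#' * `paper_scale.yaml` -- a dataset request at the study's four-class
#'   composition (300/243/272/288), not rendered.
#' Reruns are byte-identical.
#'
#' @param out Output directory.
#' @return `out`, invisibly.
#' @export
make_fixtures <- function(out) {
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out)) stop("unwritable fixture path: ", out)
  generate_dataset("four_class", c(4L, 4L, 4L, 4L),
                   file.path(out, "overfit16"), global_seed = 101L,
                   clean = TRUE)
  generate_dataset("four_class", c(16L, 16L, 16L, 16L),
                   file.path(out, "clean64"), global_seed = 202L,
                   clean = TRUE)
  yaml::write_yaml(list(scheme = "four_class",
                        class_counts = c(300L, 243L, 272L, 288L),
                        canvas = 128L, global_seed = 1L),
                   file.path(out, "paper_scale.yaml"))
  invisible(out)
}
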