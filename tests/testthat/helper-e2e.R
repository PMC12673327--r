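# Full synthetic end-to-end run (generate -> split -> binarize -> train ->
# evaluate) at the study's class compositions, used by the acceptance-style
# tests. Results are cached per (scheme, seed) within the session so the
# determinism check can re-run from scratch while the threshold checks
# reuse the first run.

e2e_cache <- new.env()

run_synthetic_e2e <- function(scheme, seed = 1L, epochs = NULL,
                              fresh = FALSE) {
  counts <- if (scheme == "four_class") c(300L, 243L, 272L, 288L)
            else c(139L, 206L, 219L, 221L, 204L, 165L)
  if (is.null(epochs)) epochs <- if (scheme == "four_class") 15L else 20L
  key <- paste(scheme, seed, epochs, sep = "_")
  if (!fresh && !is.null(e2e_cache[[key]])) return(e2e_cache[[key]])

  dir <- file.path(tempdir(), paste0("e2e_", key, if (fresh) "_fresh" else ""))
  manifest <- generate_dataset(scheme, counts, dir, global_seed = seed)
  K <- length(counts)
  cfg <- training_config(epochs = epochs, seed = seed + 1L)
  sp <- split_dataset(manifest, cfg)
  tr <- prepare_dataset(sp$train, 64L)
  te <- prepare_dataset(sp$test, 64L)
  model <- build_kromnet(kromnet_spec(K, 64L, "small"), seed = seed + 2L)
  fit <- train_kromnet(model, tr$x, tr$labels, cfg,
                       x_test = te$x, test_labels = te$labels)
  ev <- evaluate_kromnet(fit$model, te$x, te$labels)
  rep <- compute_metrics(confusion(ev$pred, te$labels, K))
  out <- list(accuracy = ev$accuracy, macro_f1 = rep$f1, report = rep,
              history = fit$history, n_train = length(tr$labels),
              n_test = length(te$labels))
  if (!fresh) e2e_cache[[key]] <- out
  out
}
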