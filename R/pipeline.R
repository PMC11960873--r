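#' Assemble a full run configuration
#'
#' Bundles the frontend, augmentation, architecture, training and
#' explanation parameters together with a global seed. The configuration
#' round-trips losslessly through YAML via [write_run_config()] /
#' [read_run_config()].
#'
#' @param frontend a [frontend_config()]
#' @param grid an [augmentation_grid()]
#' @param arch an [architecture_spec()]
#' @param train a [train_config()]
#' @param explain list of explanation parameters: `n` spectrograms per
#'   class, `g` channels per layer, `k` top channels in sample reports,
#'   `layers` to analyze (`NULL` = all conv/dense layers)
#' @param n_per_class synthetic corpus size per class (scalar or named)
#' @param seed global seed fanned out to per-stage streams
#' @return object of class `run_config`
#' @export
run_config <- function(frontend = frontend_config(),
                       grid = augmentation_grid(),
                       arch = architecture_spec(),
                       train = train_config(),
                       explain = list(n = 5L, g = 2L, k = 6L, layers = NULL),
                       n_per_class = 40L, seed = 7L) {
  structure(list(frontend = frontend, grid = grid, arch = arch,
                 train = train, explain = explain,
                 n_per_class = n_per_class, seed = as.integer(seed)),
            class = "run_config")
}

#' @rdname run_config
#' @param config a `run_config`
#' @param path YAML file path
#' @export
write_run_config <- function(config, path) {
  plain <- rapply(unclass(config), identity, how = "replace")
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("frontend", "grid", "arch", "train", "explain",
             "n_per_class", "seed")
  unknown <- setdiff(names(y), known)
  if (length(unknown) > 0)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  fe <- do.call(frontend_config, y$frontend[setdiff(names(y$frontend), "center")])
  run_config(
    frontend = fe,
    grid = augmentation_grid(y$grid$stretch_rates, y$grid$semitone_shifts),
    arch = do.call(architecture_spec,
                   y$arch[c("block_filters", "convs_per_block", "kernel",
                            "dense_units", "n_dense", "dropout_rate",
                            "n_classes", "input_shape", "width_multiplier")]),
    train = do.call(train_config,
                    y$train[setdiff(names(y$train), character(0))]),
    explain = y$explain,
    n_per_class = unlist(y$n_per_class),
    seed = y$seed)
}

conv_dense_layers <- function(net) {
  nm <- vapply(net$layers, `[[`, character(1), "name")
  ty <- vapply(net$layers, `[[`, character(1), "type")
  nm[ty %in% c("conv", "dense") & nm != "output"]
}

#' Run the full pipeline on a synthetic corpus
#'
#' Generates the corpus, runs stratified cross-validated training and
#' evaluation, computes a class-wise average relevance heatmap per class
#' with the first fold's model, and writes all artifacts (metrics JSON,
#' confusion CSV, fold checkpoints, heatmap arrays with JSON sidecars, and
#' a reproducibility record) into `out_dir`.
#'
#' @param config a [run_config()]
#' @param out_dir output directory
#' @return the [cross_validate()] report, invisibly; artifacts on disk
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(stage, ...) {
    rec <- c(list(stage = stage, time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
             list(...))
    cat(jsonlite::toJSON(rec, auto_unbox = TRUE), "\n",
        file = file.path(out_dir, "run.log"), append = TRUE)
  }
  log_stage("synth", seed = config$seed)
  corpus <- generate_corpus(config$n_per_class, seed = config$seed)
  cfg <- config$train
  cfg$seed <- derive_seed(config$seed, 2L)
  log_stage("cross_validate", k = cfg$k_folds)
  cv <- cross_validate(corpus, config$arch, cfg, config$grid, config$frontend)

  for (fold in seq_along(cv$folds)) {
    save_network(cv$folds[[fold]]$net,
                 file.path(out_dir, sprintf("fold%d.rds", fold)))
  }
  utils::write.csv(as.data.frame.matrix(cv$mean_rates),
                   file.path(out_dir, "confusion.csv"))
  jsonlite::write_json(
    list(mean_recall = cv$mean_recall,
         per_class_recall = as.list(cv$per_class_recall)),
    file.path(out_dir, "metrics.json"), auto_unbox = TRUE, digits = NA)

  log_stage("class_heatmaps")
  net <- cv$folds[[1L]]$net
  layers <- config$explain$layers %||% utils::tail(conv_dense_layers(net), 3L)
  specs_by_class <- split_corpus_logmels(corpus, config$frontend)
  for (cl in names(specs_by_class)) {
    n_use <- min(config$explain$n, length(specs_by_class[[cl]]))
    ch <- class_average_heatmap(net, specs_by_class[[cl]], cl,
                                n = n_use, g = config$explain$g,
                                layers = layers,
                                n_classes = config$arch$n_classes)
    write_array(ch$heatmap, file.path(out_dir, paste0("heatmap_", cl)),
                meta = list(class = cl, contributors = ch$contributors,
                            mbar = ch$mbar, layers = layers))
  }
  write_run_config(config, file.path(out_dir, "config.yaml"))
  jsonlite::write_json(
    list(seed = config$seed,
         r_version = as.character(getRversion()),
         package_version = as.character(utils::packageVersion("bleatr"))),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE)
  log_stage("done", mean_recall = cv$mean_recall)
  invisible(cv)
}

# one logmel (first segment of each clip) per clip, grouped by class
split_corpus_logmels <- function(corpus, config = frontend_config()) {
  lms <- lapply(corpus$clips, function(clip) clip_logmels(clip, config)[[1L]])
  labels <- vapply(corpus$clips, function(c) c$label, character(1))
  split(lms, labels)
}

# portable binary array + JSON sidecar
write_array <- function(a, stem, meta = list()) {
  con <- file(paste0(stem, ".bin"), "wb")
  writeBin(as.numeric(a), con, size = 8, endian = "little")
  close(con)
  jsonlite::write_json(c(list(dim = dim(a), storage = "float64_le"), meta),
                       paste0(stem, ".json"), auto_unbox = TRUE)
  invisible(stem)
}

#' Desk-scale cross-validation benchmark on the synthetic corpus
#'
#' The package's standard end-to-end experiment: an 8-class synthetic
#' corpus (40 clips per class by default), a width-0.125 network, and
#' stratified 5-fold cross-validation. Training uses original segments
#' only with a short schedule (6 epochs maximum, learning rate 1e-3,
#' early stopping with patience 2); see the methods vignette for why the
#' desk-scale profile differs from the full-width protocol.
#'
#' @param seed master seed
#' @param n_per_class clips per class
#' @param width network width multiplier
#' @param max_epochs training epochs cap
#' @return a [cross_validate()] report
#' @export
synthetic_benchmark <- function(seed = 7L, n_per_class = 40L, width = 0.125,
                                max_epochs = 6L) {
  corpus <- generate_corpus(n_per_class, seed = seed)
  arch <- architecture_spec(width_multiplier = width)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 12L,
                      max_epochs = max_epochs,
                      early_stopping = list(metric = "val_loss",
                                            patience = 2L),
                      k_folds = 5L, seed = seed)
  cross_validate(corpus, arch, cfg, identity_grid())
}
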