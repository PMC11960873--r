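#' Training configuration
#'
#' Defaults mirror the published learning setup: Adam with learning rate
#' 1e-4, batch size 12, at most 14 epochs with early stopping, stratified
#' 5-fold cross-validation.
#'
#' @param learning_rate Adam step size
#' @param batch_size minibatch size
#' @param max_epochs maximum training epochs (0 = no training)
#' @param early_stopping `list(metric = "val_loss", patience = 3)` or
#'   `NULL` to disable
#' @param validation_fraction fraction of training sources held out
#'   (stratified) to monitor the early-stopping metric
#' @param k_folds number of cross-validation folds
#' @param seed master seed for fold shuffling, initialization and dropout
#' @return object of class `train_config`
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 12L,
                         max_epochs = 14L,
                         early_stopping = list(metric = "val_loss",
                                               patience = 3L),
                         validation_fraction = 0.1,
                         k_folds = 5L, seed = 1L) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 0, k_folds >= 2,
            validation_fraction >= 0, validation_fraction < 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping = early_stopping,
                 validation_fraction = validation_fraction,
                 k_folds = as.integer(k_folds), seed = as.integer(seed)),
            class = "train_config")
}

#' Stratified fold assignment at the source-recording level
#'
#' Sources are shuffled within each class (seeded) and dealt round-robin to
#' the folds, so per-fold class counts differ from exact proportionality by
#' at most one source. Grouping by source recording guarantees that a
#' clip's segments and augmented variants always share a fold.
#'
#' @param manifest data.frame with columns `source_id` and `label`
#'   (one row per source)
#' @param k number of folds (>= 2)
#' @param seed integer seed
#' @return object of class `fold_plan` with an `assignments` data.frame
#'   (`source_id`, `label`, `fold`) and a per-fold class-count report
#' @export
make_folds <- function(manifest, k = 5L, seed = 1L) {
  stopifnot(is.data.frame(manifest),
            all(c("source_id", "label") %in% names(manifest)))
  if (k < 2) stop("k must be at least 2 (k = 1 leaves no held-out data)")
  manifest <- unique(manifest[, c("source_id", "label")])
  counts <- table(manifest$label)
  if (length(counts) < 2)
    stop("stratification requires at least two classes")
  short <- names(counts)[counts < k]
  if (length(short) > 0)
    stop("class(es) with fewer than k sources: ",
         paste(short, collapse = ", "))
  assignments <- with_seed(derive_seed(seed, 101L), {
    do.call(rbind, lapply(sort(unique(manifest$label)), function(cl) {
      ids <- manifest$source_id[manifest$label == cl]
      ids <- sample(ids)
      data.frame(source_id = ids, label = cl,
                 fold = rep_len(seq_len(k), length(ids)),
                 stringsAsFactors = FALSE)
    }))
  })
  report <- table(assignments$label, assignments$fold)
  structure(list(k = as.integer(k), assignments = assignments,
                 report = report, seed = as.integer(seed)),
            class = "fold_plan")
}

#' @export
print.fold_plan <- function(x, ...) {
  cat(sprintf("<fold_plan> %d folds, %d sources\n", x$k,
              nrow(x$assignments)))
  print(x$report)
  invisible(x)
}

fold_sources <- function(plan, fold, role = c("train", "test")) {
  role <- match.arg(role)
  a <- plan$assignments
  if (!fold %in% seq_len(plan$k)) stop("invalid fold index: ", fold)
  if (role == "test") a$source_id[a$fold == fold]
  else a$source_id[a$fold != fold]
}

# ---- parameter bookkeeping ---------------------------------------------

param_layers <- function(net) {
  which(vapply(net$layers, function(l) !is.null(l$W), logical(1)))
}

get_params <- function(net) {
  lapply(net$layers[param_layers(net)], function(l) list(W = l$W, b = l$b))
}

set_params <- function(net, params) {
  idx <- param_layers(net)
  for (i in seq_along(idx)) {
    net$layers[[idx[i]]]$W <- params[[i]]$W
    net$layers[[idx[i]]]$b <- params[[i]]$b
  }
  net
}

adam_init <- function(params) {
  list(m = rapply(params, function(p) p * 0, how = "replace"),
       v = rapply(params, function(p) p * 0, how = "replace"),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (i in seq_along(params)) {
    for (f in c("W", "b")) {
      g <- grads[[i]][[f]]
      state$m[[i]][[f]] <- beta1 * state$m[[i]][[f]] + (1 - beta1) * g
      state$v[[i]][[f]] <- beta2 * state$v[[i]][[f]] + (1 - beta2) * g * g
      params[[i]][[f]] <- params[[i]][[f]] -
        lr * (state$m[[i]][[f]] / c1) / (sqrt(state$v[[i]][[f]] / c2) + eps)
    }
  }
  list(params = params, state = state)
}

# Backward pass: dlogits is n_classes x N (loss gradient at the output).
# Returns per-parameter-layer gradients in param_layers() order.
backward_pass <- function(net, cache, dlogits) {
  grads <- list()
  dx <- dlogits
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cc <- cache[[i]]
    if (l$type == "dense") {
      dz <- if (identical(l$activation, "relu")) dx * (cc$output > 0) else dx
      grads[[l$name]] <- list(W = dz %*% t(cc$input), b = rowSums(dz))
      dx <- t(l$W) %*% dz
    } else if (l$type == "dropout") {
      if (!is.null(cc$mask)) dx <- dx * cc$mask
    } else if (l$type == "flatten") {
      dx <- array(dx, dim = cc$in_dim)
    } else if (l$type == "pool") {
      dx <- cpp_maxpool_backward(cc$idx, dx, as.integer(cc$in_dim))
    } else if (l$type == "conv") {
      res <- cpp_conv_backward(cc$input, l$W, cc$output, dx,
                               identical(l$activation, "relu"))
      grads[[l$name]] <- list(W = res$dw, b = res$db)
      dx <- res$dx
    }
  }
  idx <- param_layers(net)
  lapply(net$layers[idx], function(l) grads[[l$name]])
}

cross_entropy <- function(probs, y_index) {
  # probs: N x n_classes, y_index: 1-based class per row
  p <- probs[cbind(seq_len(nrow(probs)), y_index)]
  -mean(log(pmax(p, 1e-12)))
}

# Evaluate loss/accuracy on a feature array without caching.
batch_metrics <- function(net, X, y_index, chunk = 64L) {
  n <- dim(X)[4L]
  loss <- 0; correct <- 0
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    probs <- forward_pass(net, X[, , , s:e, drop = FALSE])$probs
    yy <- y_index[s:e]
    loss <- loss + cross_entropy(probs, yy) * (e - s + 1L)
    correct <- correct + sum(max.col(probs) == yy)
  }
  list(loss = loss / n, acc = correct / n)
}

# ---- feature assembly ---------------------------------------------------

# Build the (128, 44, 1, N) feature array for the given sources.
# When `grid` is non-NULL every segment is expanded into its augmentation
# variants (training data); otherwise originals only.
corpus_features <- function(corpus, source_ids, grid = NULL,
                            config = frontend_config()) {
  clips <- corpus$clips[match(source_ids, vapply(corpus$clips,
                                                 function(c) c$source_id,
                                                 character(1)))]
  specs <- list()
  for (clip in clips) {
    segs <- segment_clip(standardize_duration(clip, config), config)
    for (seg in segs) {
      if (is.null(grid)) {
        specs[[length(specs) + 1L]] <- extract_logmel(seg, config)
      } else {
        for (v in augment_segment(seg, grid, config)) {
          specs[[length(specs) + 1L]] <- extract_logmel(v, config)
        }
      }
    }
  }
  labels <- vapply(specs, function(s) s$provenance$label, character(1))
  h <- nrow(specs[[1L]]$values); w <- ncol(specs[[1L]]$values)
  X <- array(0, dim = c(h, w, 1L, length(specs)))
  for (i in seq_along(specs)) X[, , 1L, i] <- specs[[i]]$values
  list(X = X, labels = labels,
       source_ids = vapply(specs, function(s) s$provenance$source_id,
                           character(1)))
}

# ---- fold training ------------------------------------------------------

#' Train the network on one cross-validation fold
#'
#' The training set consists of all augmentation variants of the training
#' fold's segments; a stratified fraction of training sources is held out
#' to monitor validation loss for early stopping (best parameters are
#' restored). Cross-entropy loss, Adam optimizer.
#'
#' @param corpus a corpus object (see [generate_corpus()]) with `clips`
#'   and `manifest`
#' @param plan a [make_folds()] plan
#' @param fold fold index in `1..k`
#' @param spec an [architecture_spec()]
#' @param cfg a [train_config()]
#' @param grid an [augmentation_grid()]; use [identity_grid()] to train on
#'   originals only
#' @param config a [frontend_config()]
#' @return list with the trained `net` and a per-epoch `history`
#'   data.frame (train/validation loss and accuracy)
#' @export
train_fold <- function(corpus, plan, fold, spec = architecture_spec(),
                       cfg = train_config(), grid = augmentation_grid(),
                       config = frontend_config()) {
  train_ids <- fold_sources(plan, fold, "train")
  if (length(train_ids) == 0L) stop("empty training fold")
  # stratified validation split at the source level
  a <- plan$assignments
  tr <- a[a$source_id %in% train_ids, ]
  val_ids <- character(0)
  if (cfg$validation_fraction > 0 && !is.null(cfg$early_stopping)) {
    val_ids <- with_seed(derive_seed(cfg$seed, 300L + fold), {
      unlist(lapply(split(tr$source_id, tr$label), function(ids) {
        n_val <- max(1L, floor(length(ids) * cfg$validation_fraction))
        sample(ids, n_val)
      }), use.names = FALSE)
    })
  }
  fit_ids <- setdiff(train_ids, val_ids)

  feats <- corpus_features(corpus, fit_ids, grid = grid, config = config)
  classes <- sort(unique(plan$assignments$label))
  y <- match(feats$labels, classes)
  has_val <- length(val_ids) > 0
  if (has_val) {
    vf <- corpus_features(corpus, val_ids, grid = NULL, config = config)
    y_val <- match(vf$labels, classes)
  }

  if (spec$n_classes != length(classes)) {
    spec$n_classes <- as.integer(length(classes))
  }
  net <- build_network(spec, seed = derive_seed(cfg$seed, 500L + fold))
  net$classes <- classes
  params <- get_params(net)
  state <- adam_init(params)
  history <- data.frame()
  if (cfg$max_epochs == 0L) {
    return(list(net = net, history = history))
  }

  n <- dim(feats$X)[4L]
  best <- list(metric = Inf, params = params, epoch = 0L)
  patience <- if (!is.null(cfg$early_stopping)) cfg$early_stopping$patience
              else Inf
  wait <- 0L
  with_seed(derive_seed(cfg$seed, 700L + fold), {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0
      for (s in seq(1L, n, by = cfg$batch_size)) {
        e <- min(s + cfg$batch_size - 1L, n)
        idx <- ord[s:e]
        xb <- feats$X[, , , idx, drop = FALSE]
        yb <- y[idx]
        net <- set_params(net, params)
        fw <- forward_pass(net, xb, training = TRUE, keep_cache = TRUE)
        nb <- length(idx)
        ep_loss <- ep_loss + cross_entropy(fw$probs, yb) * nb
        ep_correct <- ep_correct + sum(max.col(fw$probs) == yb)
        dlogits <- t(fw$probs)
        dlogits[cbind(yb, seq_len(nb))] <-
          dlogits[cbind(yb, seq_len(nb))] - 1
        dlogits <- dlogits / nb
        grads <- backward_pass(net, fw$cache, dlogits)
        upd <- adam_step(params, grads, state, cfg$learning_rate)
        params <- upd$params
        state <- upd$state
      }
      net <- set_params(net, params)
      row <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                        train_acc = ep_correct / n,
                        val_loss = NA_real_, val_acc = NA_real_)
      if (has_val) {
        vm <- batch_metrics(net, vf$X, y_val)
        row$val_loss <- vm$loss
        row$val_acc <- vm$acc
        metric <- if (identical(cfg$early_stopping$metric, "val_acc"))
          -vm$acc else vm$loss
        if (is.finite(patience)) {
          if (metric < best$metric - 1e-9) {
            best <- list(metric = metric, params = params, epoch = epoch)
            wait <- 0L
          } else {
            wait <- wait + 1L
          }
        }
      }
      history <- rbind(history, row)
      if (is.finite(patience) && has_val && wait >= patience) break
    }
  })
  if (is.finite(patience) && has_val && best$epoch > 0L)
    params <- best$params
  net <- set_params(net, params)
  list(net = net, history = history)
}

#' Evaluate a trained network on original (non-augmented) test clips
#'
#' A clip's prediction is the argmax of the arithmetic mean of its
#' segments' softmax rows. Any augmented clip in the test set raises a
#' leakage error.
#'
#' @param net a trained `bleatr_network`
#' @param corpus a corpus object
#' @param test_ids source ids of the test clips
#' @param config a [frontend_config()]
#' @return object of class `evaluation_report`: confusion counts,
#'   row-normalized rates, per-class recall and their mean
#' @export
evaluate <- function(net, corpus, test_ids, config = frontend_config()) {
  ids <- vapply(corpus$clips, function(c) c$source_id, character(1))
  clips <- corpus$clips[match(test_ids, ids)]
  classes <- net$classes
  truth <- character(length(clips))
  pred <- character(length(clips))
  for (i in seq_along(clips)) {
    clip <- clips[[i]]
    if (!is.null(clip$augmentation))
      stop("augmented clip in test set: ", clip$source_id)
    if (is.null(clip$label)) stop("unlabeled test clip: ", clip$source_id)
    lms <- clip_logmels(clip, config)
    probs <- predict_proba(net, lms)
    truth[i] <- clip$label
    pred[i] <- classes[which.max(colMeans(probs))]
  }
  confusion <- table(factor(truth, levels = classes),
                     factor(pred, levels = classes))
  rates <- prop.table(confusion, 1L)
  rates[is.nan(rates)] <- 0
  recall <- diag(rates)
  present <- rowSums(confusion) > 0
  structure(list(confusion = confusion, rates = rates,
                 per_class_recall = recall,
                 mean_recall = mean(recall[present]),
                 n_clips = length(clips)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d clips, mean per-class recall %.3f\n",
              x$n_clips, x$mean_recall))
  print(round(x$rates, 3))
  invisible(x)
}

#' Stratified k-fold cross-validation
#'
#' Runs [train_fold()] and [evaluate()] for every fold, averages the
#' row-normalized confusion matrices over folds, and reports the mean of
#' the per-class rates (the headline classification rate).
#'
#' @inheritParams train_fold
#' @return object of class `cv_report`: per-fold reports and histories,
#'   fold-averaged rate matrix, per-class mean recall and overall mean
#' @export
cross_validate <- function(corpus, spec = architecture_spec(),
                           cfg = train_config(), grid = augmentation_grid(),
                           config = frontend_config()) {
  plan <- make_folds(corpus$manifest, k = cfg$k_folds, seed = cfg$seed)
  folds <- vector("list", plan$k)
  rates <- NULL
  for (fold in seq_len(plan$k)) {
    fit <- train_fold(corpus, plan, fold, spec, cfg, grid, config)
    rep_f <- evaluate(fit$net, corpus, fold_sources(plan, fold, "test"),
                      config)
    folds[[fold]] <- list(net = fit$net, history = fit$history,
                          report = rep_f)
    r <- unclass(rep_f$rates)
    rates <- if (is.null(rates)) r else rates + r
  }
  rates <- rates / plan$k
  recall <- diag(rates)
  structure(list(plan = plan, folds = folds, mean_rates = rates,
                 per_class_recall = recall, mean_recall = mean(recall)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %d folds, mean per-class recall %.3f\n",
              x$plan$k, x$mean_recall))
  print(round(x$per_class_recall, 3))
  invisible(x)
}
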