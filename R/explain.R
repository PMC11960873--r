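# Conditional relevance propagation.
#
# Relevance is seeded at the output layer with the target class's
# pre-softmax score and propagated backwards with layer-type-specific
# rules: the alpha1/beta0 (z+) rule for convolutions, the epsilon rule for
# fully connected layers, winner-take-all routing through max pooling, and
# identity through flatten/dropout. Biases are excluded from the rule
# denominators, so on zero-bias networks the total relevance is conserved
# exactly. Conditions restrict relevance flow to chosen channel subsets at
# named layers, which turns a plain attribution map into a concept
# (channel)-specific one; because every rule is linear in the incoming
# relevance, singleton-channel maps at a layer sum to the unconditional map.

default_rules <- function() {
  list(conv = "alphabeta", dense = "epsilon", epsilon = 1e-6)
}

#' Validate a condition set against a network
#'
#' A condition set is a named list mapping layer names to the channel (or
#' unit) indices through which relevance may flow; an empty list means
#' unconditional propagation.
#'
#' @param net a `bleatr_network`
#' @param conditions named list of integer index vectors
#' @return the validated condition set, invisibly
#' @export
validate_conditions <- function(net, conditions) {
  if (length(conditions) == 0L) return(invisible(conditions))
  lnames <- vapply(net$layers, `[[`, character(1), "name")
  for (nm in names(conditions)) {
    i <- match(nm, lnames)
    if (is.na(i)) stop("condition refers to unknown layer: ", nm)
    l <- net$layers[[i]]
    width <- if (l$type == "conv") dim(l$W)[4L]
             else if (l$type == "dense") nrow(l$W)
             else stop("conditions only apply to conv/dense layers: ", nm)
    ch <- conditions[[nm]]
    if (any(ch < 1L) || any(ch > width))
      stop("condition channel out of range for layer ", nm)
  }
  invisible(conditions)
}

# relevance at a layer output -> channel mask application
mask_channels <- function(R, allowed, type) {
  if (type == "conv") {
    full <- array(0, dim = dim(R))
    full[, , allowed, ] <- R[, , allowed, , drop = FALSE]
    full
  } else {
    out <- R * 0
    out[allowed, ] <- R[allowed, , drop = FALSE]
    out
  }
}

# epsilon-rule propagation through a dense layer (bias excluded)
lrp_dense_epsilon <- function(W, a, R_out, eps) {
  z <- W %*% a
  denom <- z + eps * ifelse(z >= 0, 1, -1)
  a * (t(W) %*% (R_out / denom))
}

# alpha1/beta0 propagation through a same-padded convolution; handles
# signed inputs via the (x+, w+) + (x-, w-) decomposition of the positive
# pre-activations.
lrp_conv_zplus <- function(W, x, R_out, eps) {
  wp <- pmax(W, 0); wn <- pmin(W, 0)
  xp <- pmax(x, 0); xn <- pmin(x, 0)
  zeros_p <- numeric(dim(W)[4L])
  z <- cpp_conv_forward(xp, wp, zeros_p, FALSE) +
       cpp_conv_forward(xn, wn, zeros_p, FALSE)
  s <- R_out / (z + eps)
  xp * cpp_conv_bwd_data(s, wp) + xn * cpp_conv_bwd_data(s, wn)
}

#' Conditional relevance propagation for one input
#'
#' Computes per-layer relevance tensors and the input-plane heatmap for a
#' given target class. Relevance is initialized at the output layer as the
#' target's pre-softmax score. Wherever `conditions` names a layer, the
#' relevance arriving at that layer's output is zeroed outside the allowed
#' channel subset before propagation continues.
#'
#' @param net a trained `bleatr_network`
#' @param x one input: `logmel_spectrogram`, matching matrix, or numeric
#'   vector for dense-only networks
#' @param target 1-based target class index or class name
#' @param conditions named list of allowed channel indices per layer
#'   (empty = unconditional)
#' @param rules propagation rules, see `default_rules()`
#' @return object of class `relevance_bundle`: `target`,
#'   `layer_relevance` (named list of relevance at each layer's output),
#'   `heatmap` (input-plane relevance), `conditions`, `rules`, and the
#'   target's pre-softmax `score`
#' @export
relevance <- function(net, x, target, conditions = list(),
                      rules = default_rules()) {
  validate_conditions(net, conditions)
  xin <- prepare_single_input(net, x)
  fw <- forward_pass(net, xin, keep_cache = TRUE)
  relevance_impl(net, fw, target, conditions, rules)
}

prepare_single_input <- function(net, x) {
  if (net$layers[[1L]]$type == "dense") {
    if (inherits(x, "logmel_spectrogram")) x <- as.numeric(x$values)
    matrix(as.numeric(x), ncol = 1L)
  } else {
    as_input_batch(x, net$spec)
  }
}

relevance_impl <- function(net, fw, target, conditions = list(),
                           rules = default_rules()) {
  if (is.character(target)) {
    target <- match(target, net$classes)
    if (is.na(target)) stop("unknown target class")
  }
  eps <- rules$epsilon %||% 1e-6
  logits <- fw$logits[1L, ]
  n_layers <- length(net$layers)
  R <- matrix(0, length(logits), 1L)
  R[target, 1L] <- logits[target]
  layer_relevance <- list()
  for (i in rev(seq_len(n_layers))) {
    l <- net$layers[[i]]
    cc <- fw$cache[[i]]
    if (!is.null(conditions[[l$name]]))
      R <- mask_channels(R, conditions[[l$name]], l$type)
    layer_relevance[[l$name]] <- drop_sample_dim(R, l$type)
    if (l$type == "dense") {
      rule <- if (identical(l$name, "output")) "epsilon" else rules$dense
      R <- switch(rule,
        epsilon = lrp_dense_epsilon(l$W, cc$input, R, eps),
        stop("unknown dense rule: ", rule))
    } else if (l$type == "conv") {
      R <- switch(rules$conv,
        alphabeta = lrp_conv_zplus(l$W, cc$input, R, eps),
        epsilon = {
          z <- cpp_conv_forward(cc$input, l$W, numeric(dim(l$W)[4L]), FALSE)
          s <- R / (z + eps * ifelse(z >= 0, 1, -1))
          cc$input * cpp_conv_bwd_data(s, l$W)
        },
        stop("unknown conv rule: ", rules$conv))
    } else if (l$type == "pool") {
      R <- cpp_maxpool_backward(cc$idx, R, as.integer(cc$in_dim))
    } else if (l$type == "flatten") {
      R <- array(R, dim = cc$in_dim)
    } else if (l$type == "dropout") {
      # identity in inference mode
    }
  }
  heatmap <- if (length(dim(R)) == 4L) R[, , 1L, 1L] else drop(R)
  structure(list(target = target, layer_relevance = layer_relevance,
                 heatmap = heatmap, conditions = conditions, rules = rules,
                 score = logits[target]),
            class = "relevance_bundle")
}

drop_sample_dim <- function(R, type) {
  if (type == "conv" || type == "pool") {
    if (length(dim(R)) == 4L) R[, , , 1L, drop = TRUE] else R
  } else if (is.matrix(R)) {
    drop(R)
  } else R
}

#' @export
print.relevance_bundle <- function(x, ...) {
  cat(sprintf("<relevance_bundle> target %d (score %.4f), %d layers%s\n",
              x$target, x$score, length(x$layer_relevance),
              if (length(x$conditions)) paste0(", conditions on ",
                paste(names(x$conditions), collapse = ", ")) else ""))
  invisible(x)
}

#' Rank the channels of a layer by total relevance
#'
#' A channel's score is the sum of the layer's relevance tensor over all
#' spatial positions of that channel; channels are returned in descending
#' score order with ties broken by ascending channel index.
#'
#' @param net a trained `bleatr_network`
#' @param x one input (see [relevance()])
#' @param target target class index or name
#' @param layer name of a conv or dense layer
#' @return object of class `channel_ranking`: data.frame with `channel`
#'   and `score`
#' @export
rank_channels <- function(net, x, target, layer) {
  bundle <- relevance(net, x, target)
  ranking_from_bundle(bundle, layer)
}

ranking_from_bundle <- function(bundle, layer) {
  tens <- bundle$layer_relevance[[layer]]
  if (is.null(tens)) stop("unknown layer: ", layer)
  scores <- if (is.null(dim(tens))) as.numeric(tens)
            else apply(tens, length(dim(tens)), sum)
  ord <- order(-scores, seq_along(scores))
  structure(data.frame(channel = ord, score = scores[ord]),
            class = c("channel_ranking", "data.frame"))
}

#' Sample-wise explanation report: top-k channels per layer
#'
#' For each named layer, ranks the channels by relevance and renders the
#' conditional input heatmap of each of the top `k` channels.
#'
#' @param net a trained `bleatr_network`
#' @param x one input
#' @param target target class index or name
#' @param layers character vector of conv/dense layer names
#' @param k channels per layer (default 6)
#' @return named list per layer: `ranking` (full), `channels`, `scores`
#'   and `heatmaps` (list of k input-plane maps)
#' @export
sample_report <- function(net, x, target, layers, k = 6L) {
  xin <- prepare_single_input(net, x)
  fw <- forward_pass(net, xin, keep_cache = TRUE)
  bundle <- relevance_impl(net, fw, target)
  out <- list()
  for (layer in layers) {
    rk <- ranking_from_bundle(bundle, layer)
    if (k > nrow(rk)) stop("k exceeds the width of layer ", layer)
    top <- utils::head(rk, k)
    heatmaps <- lapply(top$channel, function(ch) {
      cond <- stats::setNames(list(ch), layer)
      relevance_impl(net, fw, target, conditions = cond)$heatmap
    })
    out[[layer]] <- list(ranking = rk, channels = top$channel,
                         scores = top$score, heatmaps = heatmaps)
  }
  out
}

#' Select the most central spectrograms of a class
#'
#' Flattens the spectrograms, computes the class centroid (k-means with
#' k = 1, i.e. the mean) and returns the `n` samples closest to it in
#' Euclidean distance, ties broken by corpus order.
#'
#' @param spectrograms list of `logmel_spectrogram` objects of one class
#' @param n number of samples to select
#' @return list with `spectrograms` (the selected subset), `indices` into
#'   the input list, and their `distances` to the centroid
#' @export
select_central <- function(spectrograms, n) {
  if (n > length(spectrograms))
    stop("cannot select ", n, " samples from a class of ",
         length(spectrograms))
  flat <- vapply(spectrograms, function(s) as.numeric(s$values),
                 numeric(length(spectrograms[[1L]]$values)))
  centroid <- rowMeans(flat)
  d <- sqrt(colSums((flat - centroid)^2))
  ord <- order(d) # stable: ties keep input order
  idx <- ord[seq_len(n)]
  list(spectrograms = spectrograms[idx], indices = idx, distances = d[idx])
}

#' Class-wise average relevance heatmap
#'
#' For each of the `n` most central spectrograms of a class and each
#' configured layer, computes the conditional heatmaps of the top `g`
#' channels and averages all collected maps arithmetically. The
#' `contributors` field records the number of maps actually aggregated
#' (`n * g * length(layers)`); `mbar` records the nominal per-class
#' heatmap budget `|D| * n * g`.
#'
#' @param net a trained `bleatr_network`
#' @param spectrograms list of `logmel_spectrogram` objects of one class
#' @param class_id target class index or name for the relevance target
#' @param n spectrograms per class to aggregate
#' @param g channels per layer
#' @param layers conv/dense layer names to analyze
#' @param n_classes class-dictionary cardinality used in the nominal
#'   budget
#' @return object of class `class_heatmap`
#' @export
class_average_heatmap <- function(net, spectrograms, class_id, n = 10L,
                                  g = 4L, layers, n_classes = 8L) {
  sel <- select_central(spectrograms, n)
  total <- NULL
  count <- 0L
  for (s in sel$spectrograms) {
    xin <- prepare_single_input(net, s)
    fw <- forward_pass(net, xin, keep_cache = TRUE)
    bundle <- relevance_impl(net, fw, class_id)
    for (layer in layers) {
      rk <- ranking_from_bundle(bundle, layer)
      top <- utils::head(rk$channel, g)
      for (ch in top) {
        cond <- stats::setNames(list(ch), layer)
        h <- relevance_impl(net, fw, class_id, conditions = cond)$heatmap
        total <- if (is.null(total)) h else total + h
        count <- count + 1L
      }
    }
  }
  structure(list(class_id = class_id, heatmap = total / count,
                 contributors = count,
                 mbar = n_classes * n * g,
                 n = n, g = g, layers = layers),
            class = "class_heatmap")
}

#' @export
print.class_heatmap <- function(x, ...) {
  cat(sprintf("<class_heatmap> class %s: %d contributing maps (nominal budget %d)\n",
              as.character(x$class_id), x$contributors, x$mbar))
  invisible(x)
}
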