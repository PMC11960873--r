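#' Architecture specification for the spectrogram CNN
#'
#' A VGG-style topology: four blocks of two same-padded 3x3 convolutions
#' (ReLU) followed by 2x2/stride-2 max pooling, with nominal filter counts
#' 64, 64, 128, 128, 256, 256, 512, 512; the pooled maps are flattened and
#' passed through two 4096-unit fully connected ReLU layers, dropout, and
#' an 8-way softmax output. A width multiplier scales conv filters and
#' dense units jointly for desk-scale experiments.
#'
#' @param block_filters nominal filters of the four blocks
#' @param convs_per_block convolutions per block
#' @param kernel square kernel size (odd)
#' @param dense_units nominal units of each fully connected layer
#' @param n_dense number of fully connected layers
#' @param dropout_rate dropout fraction applied after the dense stack
#' @param n_classes output classes (the 8-entry class dictionary)
#' @param input_shape `(n_mels, n_frames, channels)` of one spectrogram
#' @param width_multiplier width scale in `(0, 1]`
#' @return object of class `architecture_spec`
#' @export
architecture_spec <- function(block_filters = c(64L, 128L, 256L, 512L),
                              convs_per_block = 2L, kernel = 3L,
                              dense_units = 4096L, n_dense = 2L,
                              dropout_rate = 0.5, n_classes = 8L,
                              input_shape = c(128L, 44L, 1L),
                              width_multiplier = 1.0) {
  stopifnot(length(block_filters) >= 1, convs_per_block >= 1,
            kernel %% 2 == 1, dense_units >= 1, n_dense >= 1,
            dropout_rate >= 0, dropout_rate < 1, n_classes >= 2,
            length(input_shape) == 3,
            width_multiplier > 0, width_multiplier <= 1)
  eff_filters <- pmax(1L, as.integer(round(width_multiplier * block_filters)))
  eff_dense <- max(1L, as.integer(round(width_multiplier * dense_units)))
  h <- input_shape[1]; w <- input_shape[2]
  for (b in seq_along(block_filters)) {
    h <- h %/% 2L; w <- w %/% 2L
    if (h < 1L || w < 1L)
      stop("input shape too small to survive ", length(block_filters),
           " pooling stages")
  }
  structure(list(block_filters = as.integer(block_filters),
                 convs_per_block = as.integer(convs_per_block),
                 kernel = as.integer(kernel),
                 dense_units = as.integer(dense_units),
                 n_dense = as.integer(n_dense),
                 dropout_rate = dropout_rate,
                 n_classes = as.integer(n_classes),
                 input_shape = as.integer(input_shape),
                 width_multiplier = width_multiplier,
                 eff_filters = eff_filters,
                 eff_dense = eff_dense),
            class = "architecture_spec")
}

#' Build a seeded network from an architecture specification
#'
#' He-initialized weights, zero biases; the same `(spec, seed)` pair always
#' yields bit-identical parameters. Layers are named `conv<b>_<j>`,
#' `pool<b>`, `flatten`, `fc<k>`, `dropout`, `output`.
#'
#' @param spec an [architecture_spec()]
#' @param seed integer seed for weight initialization
#' @return object of class `bleatr_network`
#' @export
build_network <- function(spec = architecture_spec(), seed = 1L) {
  with_seed(derive_seed(seed, 77L), {
    layers <- list()
    h <- spec$input_shape[1]; w <- spec$input_shape[2]
    cin <- spec$input_shape[3]
    k <- spec$kernel
    for (b in seq_along(spec$eff_filters)) {
      f <- spec$eff_filters[b]
      for (j in seq_len(spec$convs_per_block)) {
        W <- array(rnorm(k * k * cin * f, sd = sqrt(2 / (k * k * cin))),
                   dim = c(k, k, cin, f))
        layers[[length(layers) + 1L]] <-
          list(type = "conv", name = sprintf("conv%d_%d", b, j),
               W = W, b = numeric(f), activation = "relu")
        cin <- f
      }
      layers[[length(layers) + 1L]] <-
        list(type = "pool", name = sprintf("pool%d", b))
      h <- h %/% 2L; w <- w %/% 2L
    }
    flat_dim <- h * w * cin
    layers[[length(layers) + 1L]] <-
      list(type = "flatten", name = "flatten", in_dim = c(h, w, cin))
    din <- flat_dim
    for (kk in seq_len(spec$n_dense)) {
      layers[[length(layers) + 1L]] <-
        list(type = "dense", name = sprintf("fc%d", kk),
             W = matrix(rnorm(spec$eff_dense * din, sd = sqrt(2 / din)),
                        spec$eff_dense, din),
             b = numeric(spec$eff_dense), activation = "relu")
      din <- spec$eff_dense
    }
    layers[[length(layers) + 1L]] <-
      list(type = "dropout", name = "dropout", rate = spec$dropout_rate)
    layers[[length(layers) + 1L]] <-
      list(type = "dense", name = "output",
           W = matrix(rnorm(spec$n_classes * din, sd = sqrt(2 / din)),
                      spec$n_classes, din),
           b = numeric(spec$n_classes), activation = "linear")
    structure(list(spec = spec, layers = layers, seed = seed,
                   classes = if (spec$n_classes == 8L) class_dictionary()
                             else paste0("class", seq_len(spec$n_classes))),
              class = "bleatr_network")
  })
}

#' Build a small fully connected network from explicit parameters
#'
#' Constructs a network consisting only of dense layers (the last one
#' linear, acting as the output layer). Used for hand-checkable relevance
#' propagation examples and conservation tests.
#'
#' @param weights list of weight matrices, each `out x in`
#' @param biases list of bias vectors (defaults to zeros)
#' @param activations character vector of activations for the hidden
#'   layers (`"relu"` or `"linear"`); the final layer is always linear
#' @return object of class `bleatr_network`
#' @export
dense_network <- function(weights, biases = NULL,
                          activations = rep("relu", length(weights) - 1L)) {
  stopifnot(length(weights) >= 1L)
  n <- length(weights)
  if (is.null(biases)) biases <- lapply(weights, function(W) numeric(nrow(W)))
  layers <- vector("list", n)
  for (i in seq_len(n)) {
    act <- if (i == n) "linear" else activations[i]
    nm <- if (i == n) "output" else sprintf("fc%d", i)
    layers[[i]] <- list(type = "dense", name = nm, W = weights[[i]],
                        b = biases[[i]], activation = act)
  }
  n_out <- nrow(weights[[n]])
  structure(list(spec = list(n_classes = n_out,
                             input_shape = ncol(weights[[1L]])),
                 layers = layers, seed = NA_integer_,
                 classes = paste0("class", seq_len(n_out))),
            class = "bleatr_network")
}

#' @export
print.bleatr_network <- function(x, ...) {
  cat(sprintf("<bleatr_network> %d layers, %d classes, %s parameters\n",
              length(x$layers), x$spec$n_classes,
              format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Total number of trainable parameters
#'
#' @param net a `bleatr_network`
#' @return integer parameter count
#' @export
count_parameters <- function(net) {
  sum(vapply(net$layers, function(l) {
    if (!is.null(l$W)) length(l$W) + length(l$b) else 0L
  }, numeric(1)))
}

# Coerce assorted spectrogram inputs into the (H, W, C, N) batch array the
# kernels expect.
as_input_batch <- function(x, spec) {
  if (inherits(x, "logmel_spectrogram")) x <- list(x)
  if (is.list(x) && length(x) > 0 && inherits(x[[1L]], "logmel_spectrogram")) {
    h <- nrow(x[[1L]]$values); w <- ncol(x[[1L]]$values)
    arr <- array(0, dim = c(h, w, 1L, length(x)))
    for (i in seq_along(x)) arr[, , 1L, i] <- x[[i]]$values
    return(arr)
  }
  if (is.matrix(x) && length(spec$input_shape) == 3 &&
      all(dim(x) == spec$input_shape[1:2])) {
    return(array(x, dim = c(dim(x), 1L, 1L)))
  }
  if (is.array(x) && length(dim(x)) == 4L) return(x)
  if (is.array(x) && length(dim(x)) == 3L) return(array(x, dim = c(dim(x), 1L)))
  stop("cannot interpret input as a spectrogram batch")
}

# Forward pass through the layer list.
# x: (H,W,C,N) array for conv-first nets, or (features x N) matrix /
# vector for dense-first nets. Returns logits/probs as N x n_classes,
# embedding = activation of the last hidden dense layer, and (optionally)
# per-layer caches for backprop and relevance propagation.
forward_pass <- function(net, x, training = FALSE, keep_cache = FALSE) {
  if (is.null(dim(x)) && net$layers[[1L]]$type == "dense")
    x <- matrix(x, ncol = 1L)
  cache <- if (keep_cache) vector("list", length(net$layers)) else NULL
  embedding <- NULL
  embed_name <- last_hidden_dense(net)
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    input <- x
    if (l$type == "conv") {
      x <- cpp_conv_forward(x, l$W, l$b, identical(l$activation, "relu"))
    } else if (l$type == "pool") {
      res <- cpp_maxpool_forward(x)
      if (keep_cache) cache[[i]] <- list(idx = res$idx, in_dim = dim(input))
      x <- res$y
    } else if (l$type == "flatten") {
      d <- dim(x)
      if (keep_cache) cache[[i]] <- list(in_dim = d)
      x <- matrix(x, prod(d[1:3]), d[4])
    } else if (l$type == "dense") {
      z <- l$W %*% x + l$b
      x <- if (identical(l$activation, "relu")) pmax(z, 0) else z
    } else if (l$type == "dropout") {
      if (training && l$rate > 0) {
        mask <- matrix(runif(length(x)) >= l$rate, nrow(x), ncol(x)) /
          (1 - l$rate)
        if (keep_cache) cache[[i]] <- list(mask = mask)
        x <- x * mask
      }
    } else {
      stop("unknown layer type: ", l$type)
    }
    if (keep_cache) {
      cache[[i]] <- c(cache[[i]], list(input = input, output = x))
    }
    if (identical(l$name, embed_name)) embedding <- x
  }
  logits <- t(x) # N x n_classes
  list(logits = logits, probs = t(softmax_cols(x)), embedding = embedding,
       cache = cache)
}

last_hidden_dense <- function(net) {
  nm <- NULL
  for (l in net$layers) if (l$type == "dense" && l$name != "output") nm <- l$name
  nm
}

#' Class-probability predictions for a batch of spectrograms
#'
#' Runs the network in inference mode (dropout disabled); each row of the
#' result is a softmax distribution over the class dictionary.
#'
#' @param net a `bleatr_network`
#' @param x a `logmel_spectrogram`, list of them, or `(H,W,C,N)` array
#' @param chunk maximum batch size per kernel call (memory control)
#' @return `N x n_classes` matrix of probabilities, columns named by class
#' @export
predict_proba <- function(net, x, chunk = 64L) {
  arr <- as_input_batch(x, net$spec)
  n <- dim(arr)[4L]
  out <- matrix(NA_real_, n, net$spec$n_classes,
                dimnames = list(NULL, net$classes))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    out[s:e, ] <- forward_pass(net, arr[, , , s:e, drop = FALSE])$probs
  }
  out
}

#' Embedding-space representation of spectrograms
#'
#' Returns the post-ReLU activation of the last hidden fully connected
#' layer, the representation used for similarity retrieval.
#'
#' @param net a `bleatr_network`
#' @param x spectrogram input as in [predict_proba()]
#' @param chunk maximum batch size per kernel call
#' @return `embedding_dim x N` matrix (a vector for a single input)
#' @export
embed <- function(net, x, chunk = 64L) {
  arr <- as_input_batch(x, net$spec)
  n <- dim(arr)[4L]
  cols <- NULL
  for (s in seq(1L, n, by = chunk)) {
    e <- min(s + chunk - 1L, n)
    fw <- forward_pass(net, arr[, , , s:e, drop = FALSE])
    cols <- cbind(cols, fw$embedding)
  }
  if (n == 1L) drop(cols) else cols
}

#' Save a network checkpoint
#'
#' Writes the parameters as an RDS file plus a JSON sidecar holding the
#' architecture specification.
#'
#' @param net a `bleatr_network`
#' @param path output path (`.rds`)
#' @return `path`, invisibly
#' @export
save_network <- function(net, path) {
  saveRDS(net, path)
  jsonlite::write_json(net$spec[setdiff(names(net$spec), "class")],
                       paste0(tools::file_path_sans_ext(path), "_spec.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Load a network checkpoint saved by [save_network()]
#'
#' @param path path to the `.rds` checkpoint
#' @return a `bleatr_network`
#' @export
load_network <- function(path) {
  net <- readRDS(path)
  stopifnot(inherits(net, "bleatr_network"))
  net
}
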