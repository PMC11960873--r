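# Shared fixtures, memoized so expensive objects (trained networks) are
# built once per test run.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (!exists(key, envir = .fixtures)) assign(key, force(expr), envir = .fixtures)
  get(key, envir = .fixtures)
}

# A pure tone wrapped as a 1-s segment.
tone_segment <- function(freq = 440, amp = 0.5, rate = 22050L) {
  t <- (seq_len(rate) - 1) / rate
  audio_clip(amp * sin(2 * pi * freq * t), rate, source_id = "tone")
}

# Dominant frequency of a clip via FFT peak.
peak_frequency <- function(clip) {
  sp <- Mod(stats::fft(clip$samples))
  half <- seq_len(length(clip$samples) %/% 2L)
  (which.max(sp[half]) - 1L) * clip$rate / length(clip$samples)
}

# Three acoustically well-separated classes, small corpus.
tiny_specs <- function() {
  default_specs()[c("heat", "social_isolation", "mother_kid_separation")]
}

tiny_corpus <- function() {
  memo("tiny_corpus", {
    specs <- tiny_specs()
    generate_corpus(stats::setNames(rep(8L, 3L), names(specs)), seed = 11L,
                    specs = specs)
  })
}

# A small full-input-shape architecture for fast training tests.
tiny_arch <- function() {
  architecture_spec(block_filters = c(4L, 6L, 8L, 8L), dense_units = 32L)
}

# One trained fold on the tiny corpus, shared across training/interact tests.
tiny_trained <- function() {
  memo("tiny_trained", {
    corpus <- tiny_corpus()
    plan <- make_folds(corpus$manifest, k = 2L, seed = 11L)
    cfg <- train_config(learning_rate = 1e-3, batch_size = 6L,
                        max_epochs = 16L, early_stopping = NULL,
                        validation_fraction = 0, k_folds = 2L, seed = 11L)
    fit <- train_fold(corpus, plan, 1L, tiny_arch(), cfg, identity_grid())
    list(corpus = corpus, plan = plan, cfg = cfg, net = fit$net,
         history = fit$history)
  })
}

# A small random (untrained) CNN on a reduced input for relevance tests.
small_cnn <- function(seed = 2L) {
  build_network(architecture_spec(block_filters = c(4L, 6L, 8L, 8L),
                                  dense_units = 16L,
                                  input_shape = c(32L, 16L, 1L)),
                seed = seed)
}

small_input <- function(seed = 9L) {
  set.seed(seed)
  array(rnorm(32 * 16), dim = c(32L, 16L, 1L, 1L))
}

layer_width <- function(net, layer) {
  for (l in net$layers) {
    if (identical(l$name, layer)) {
      return(if (l$type == "conv") dim(l$W)[4L] else nrow(l$W))
    }
  }
  stop("no such layer: ", layer)
}

# Wrap a plain 128 x 44 matrix as a logmel object for functions that want one.
as_logmel <- function(values, source_id = "x", label = NULL) {
  structure(list(values = values, config = frontend_config(),
                 provenance = list(source_id = source_id,
                                   segment_index = 1L, label = label,
                                   augmentation = NULL)),
            class = "logmel_spectrogram")
}

# The desk-scale cross-validated model (40 clips/class, width 0.125,
# seed 7): trained once per test run and shared by the acceptance checks.
acceptance_model <- function() {
  memo("acceptance_model", {
    corpus <- generate_corpus(40L, seed = 7L)
    cv <- synthetic_benchmark(seed = 7L)
    list(corpus = corpus, cv = cv, net = cv$folds[[1L]]$net,
         plan = cv$plan)
  })
}
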