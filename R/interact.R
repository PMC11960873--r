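# The four-question interactive explanation interface: influence maps with
# sonification, similarity / dissimilarity retrieval in embedding space,
# and sonified relevance differences between two vocalizations.

#' Threshold a relevance heatmap into a region mask
#'
#' The mask selects cells whose relevance lies at or above the `p`-th
#' percentile of the positive relevance values; `p = 0` keeps every
#' positive-relevance cell.
#'
#' @param heatmap input-plane relevance matrix
#' @param p percentile threshold in `[0, 100]`
#' @return object of class `region_mask`: binary `mask` matrix of the same
#'   shape, the `percentile` and the numeric `threshold` used
#' @export
region_mask <- function(heatmap, p = 90) {
  stopifnot(p >= 0, p <= 100)
  pos <- heatmap[heatmap > 0]
  if (length(pos) == 0L) {
    mask <- matrix(0, nrow(heatmap), ncol(heatmap))
    thr <- Inf
  } else {
    thr <- stats::quantile(pos, p / 100, names = FALSE)
    mask <- (heatmap > 0 & heatmap >= thr) * 1
  }
  structure(list(mask = mask, percentile = p, threshold = thr),
            class = "region_mask")
}

#' Time-frequency extents of a region mask
#'
#' @param mask a [region_mask()]
#' @param config a [frontend_config()]
#' @return list with `time` (seconds, frame-center range) and `freq`
#'   (Hz, mel-band-center range), or `NULL`s for an empty mask
#' @export
mask_extents <- function(mask, config = frontend_config()) {
  m <- mask$mask
  rows <- which(rowSums(m) > 0)
  cols <- which(colSums(m) > 0)
  if (length(rows) == 0L) return(list(time = NULL, freq = NULL))
  fb <- mel_filterbank(config$n_mels, config$win_length, config$sample_rate,
                       scale = config$mel_scale)
  cf <- attr(fb, "center_freqs")
  list(time = (range(cols) - 1L) * config$hop_length / config$sample_rate,
       freq = cf[range(rows)])
}

#' Sonify a masked time-frequency region of a segment
#'
#' Lifts the mel-plane mask to the linear STFT plane through the
#' pseudo-inverse of the mel filterbank (clipped to `[0, 1]`), multiplies
#' the segment's STFT magnitudes by the lifted mask, and resynthesizes
#' with the original phases, so only the selected content remains audible.
#'
#' @param clip the 1-second [audio_clip()] segment the mask was computed on
#' @param mask a [region_mask()] (or a bare mel-plane matrix in `[0, 1]`)
#' @param config a [frontend_config()]
#' @return an [audio_clip()] of the same length as the input
#' @export
sonify_region <- function(clip, mask, config = frontend_config()) {
  m <- if (inherits(mask, "region_mask")) mask$mask else mask
  sp <- stft(clip$samples, config$win_length, config$hop_length,
             config$center)
  if (!all(dim(m) == c(config$n_mels, ncol(sp))))
    stop("mask shape does not match the segment's spectrogram")
  fb <- mel_filterbank(config$n_mels, config$win_length, config$sample_rate,
                       scale = config$mel_scale)
  lift <- pinv(fb) %*% m
  # normalize by the lifted all-ones mask so a full mask is transparent
  ones <- pinv(fb) %*% matrix(1, nrow(m), ncol(m))
  nz <- abs(ones) > 1e-6
  lift[nz] <- lift[nz] / ones[nz]
  lift <- pmin(pmax(lift, 0), 1)
  y <- istft(sp * lift, config$win_length, config$hop_length, config$center,
             length = length(clip$samples))
  out <- clip
  out$samples <- y
  out
}

# Pick the 1-s segment whose prediction drives the clip-level decision:
# the segment with the highest probability for the clip's predicted class.
influence_segment <- function(net, clip, config) {
  segs <- segment_clip(standardize_duration(clip, config), config)
  lms <- lapply(segs, extract_logmel, config = config)
  probs <- predict_proba(net, lms)
  cls <- which.max(colMeans(probs))
  seg_i <- which.max(probs[, cls])
  list(segment = segs[[seg_i]], logmel = lms[[seg_i]], class_index = cls,
       clip_probs = colMeans(probs))
}

#' Question 1: which spectrogram content drove this prediction?
#'
#' Runs relevance propagation for the predicted class on the segment that
#' drives the clip-level decision, thresholds the heatmap into a
#' high-significance region mask, reports the region's time-frequency
#' extents, and sonifies the masked content.
#'
#' @param net a trained `bleatr_network`
#' @param clip an [audio_clip()]
#' @param p percentile for the region mask (default 90)
#' @param config a [frontend_config()]
#' @return list: predicted `class`, clip `probs`, `heatmap`, `mask`,
#'   `extents` (seconds / Hz) and sonified `audio`
#' @export
answer_influence <- function(net, clip, p = 90, config = frontend_config()) {
  sel <- influence_segment(net, clip, config)
  bundle <- relevance(net, sel$logmel, sel$class_index)
  mask <- region_mask(bundle$heatmap, p)
  list(class = net$classes[sel$class_index], probs = sel$clip_probs,
       heatmap = bundle$heatmap, mask = mask,
       extents = mask_extents(mask, config),
       audio = sonify_region(sel$segment, mask, config),
       segment = sel$segment)
}

#' Embedding matrix of a corpus
#'
#' A clip's embedding is the arithmetic mean of its segments' embeddings
#' (the last hidden fully connected layer's activations).
#'
#' @param net a trained `bleatr_network`
#' @param corpus a corpus object with `clips`
#' @param config a [frontend_config()]
#' @return `embedding_dim x n_clips` matrix with source ids as column names
#' @export
corpus_embeddings <- function(net, corpus, config = frontend_config()) {
  cols <- vapply(corpus$clips, function(clip) {
    e <- embed(net, clip_logmels(clip, config))
    if (is.matrix(e)) rowMeans(e) else e
  }, numeric(embedding_dim(net)))
  colnames(cols) <- vapply(corpus$clips, function(c) c$source_id,
                           character(1))
  cols
}

embedding_dim <- function(net) {
  nm <- last_hidden_dense(net)
  for (l in net$layers) if (identical(l$name, nm)) return(nrow(l$W))
  stop("network has no hidden dense layer")
}

cosine_distance <- function(q, E) {
  qn <- sqrt(sum(q^2))
  en <- sqrt(colSums(E^2))
  sim <- as.numeric(crossprod(E, q)) / pmax(en * qn, 1e-12)
  1 - sim
}

#' Questions 2 and 3: most similar / dissimilar corpus vocalizations
#'
#' Computes cosine distances between the query clip's embedding and every
#' corpus embedding, and returns the `top_k` closest (similar) or farthest
#' (dissimilar) entries with their distances.
#'
#' @param net a trained `bleatr_network`
#' @param clip query [audio_clip()]
#' @param corpus a corpus object, or a precomputed [corpus_embeddings()]
#'   matrix
#' @param top_k number of neighbors to return
#' @param config a [frontend_config()]
#' @return object of class `neighbor_list`: data.frame `id`, `distance`
#' @export
find_similar <- function(net, clip, corpus, top_k = 5L,
                         config = frontend_config()) {
  neighbor_query(net, clip, corpus, top_k, decreasing = FALSE, config)
}

#' @rdname find_similar
#' @export
find_dissimilar <- function(net, clip, corpus, top_k = 5L,
                            config = frontend_config()) {
  neighbor_query(net, clip, corpus, top_k, decreasing = TRUE, config)
}

neighbor_query <- function(net, clip, corpus, top_k, decreasing, config) {
  E <- if (is.matrix(corpus)) corpus else corpus_embeddings(net, corpus, config)
  if (ncol(E) == 0L) stop("empty corpus")
  e <- embed(net, clip_logmels(clip, config))
  q <- if (is.matrix(e)) rowMeans(e) else e
  d <- cosine_distance(q, E)
  ord <- order(d, decreasing = decreasing)
  top <- utils::head(ord, top_k)
  structure(data.frame(id = colnames(E)[top], distance = d[top],
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("neighbor_list", "data.frame"),
            direction = if (decreasing) "dissimilar" else "similar",
            query = clip$source_id)
}

#' Question 4: sonified relevance difference between two vocalizations
#'
#' Computes each clip's relevance heatmap for its own predicted class,
#' min-max normalizes both maps to `[0, 1]` so recordings of different
#' energy are comparable, subtracts them, masks the cells whose absolute
#' difference exceeds the `p`-th percentile, and sonifies the masked
#' regions of both clips.
#'
#' @param net a trained `bleatr_network`
#' @param clip_a,clip_b two [audio_clip()] inputs
#' @param p percentile threshold on the absolute difference (default 90)
#' @param config a [frontend_config()]
#' @return list: `difference` map (a minus b), `mask`, predicted
#'   `classes`, and `sonified` list with members `a` and `b`
#' @export
relevance_difference <- function(net, clip_a, clip_b, p = 90,
                                 config = frontend_config()) {
  sa <- influence_segment(net, clip_a, config)
  sb <- influence_segment(net, clip_b, config)
  ha <- minmax01(relevance(net, sa$logmel, sa$class_index)$heatmap)
  hb <- minmax01(relevance(net, sb$logmel, sb$class_index)$heatmap)
  d <- ha - hb
  absd <- abs(d)
  pos <- absd[absd > 0]
  if (length(pos) == 0L) {
    mask <- structure(list(mask = d * 0, percentile = p, threshold = Inf),
                      class = "region_mask")
  } else {
    thr <- stats::quantile(pos, p / 100, names = FALSE)
    mask <- structure(list(mask = (absd > 0 & absd >= thr) * 1,
                           percentile = p, threshold = thr),
                      class = "region_mask")
  }
  list(difference = d, mask = mask,
       classes = net$classes[c(sa$class_index, sb$class_index)],
       sonified = list(a = sonify_region(sa$segment, mask, config),
                       b = sonify_region(sb$segment, mask, config)))
}

minmax01 <- function(h) {
  rng <- range(h)
  if (diff(rng) < 1e-12) return(h * 0)
  (h - rng[1]) / diff(rng)
}
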