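#' The eight-context class dictionary
#'
#' Labels for the eight situational / emotional contexts in which goat
#' vocalizations are recorded on farm: heat, feed distribution, parturition,
#' injury or death, social isolation, mother-kid reunion, presence of
#' unknown visitors, and mother-kid separation.
#'
#' @return character vector of the 8 class identifiers, in canonical order
#' @export
class_dictionary <- function() {
  c("heat", "feed_distribution", "parturition", "injury_death",
    "social_isolation", "mother_kid_reunion", "unknown_visitors",
    "mother_kid_separation")
}

#' Frontend configuration
#'
#' Parameters of the audio standardization and log-Mel extraction stage.
#' Defaults: 22050 Hz sample rate, 2-s clips, 1-s analysis segments with
#' 50% overlap, 128 mel bands, 1024-sample analysis window with 512-sample
#' hop (50% STFT overlap), natural-log compression with additive floor.
#'
#' @param sample_rate sample rate in Hz
#' @param clip_duration standardized clip duration in seconds
#' @param segment_duration analysis segment duration in seconds
#' @param segment_overlap fractional overlap between successive segments
#' @param n_mels number of mel bands
#' @param win_length STFT window length in samples
#' @param hop_length STFT hop in samples; must equal `win_length / 2`
#' @param log_floor additive power floor before the logarithm
#' @param mel_scale `"slaney"` or `"htk"` mel scale variant
#' @param center center STFT frames on multiples of the hop
#' @return object of class `frontend_config`
#' @export
frontend_config <- function(sample_rate = 22050L, clip_duration = 2.0,
                            segment_duration = 1.0, segment_overlap = 0.5,
                            n_mels = 128L, win_length = 1024L,
                            hop_length = 512L, log_floor = 1e-10,
                            mel_scale = c("slaney", "htk"), center = TRUE) {
  mel_scale <- match.arg(mel_scale)
  stopifnot(sample_rate > 0, clip_duration > 0, segment_duration > 0,
            segment_overlap >= 0, segment_overlap < 1,
            n_mels > 0, win_length > 0, log_floor > 0)
  if (hop_length != win_length / 2)
    stop("hop_length must be win_length / 2 (50% window overlap)")
  structure(list(sample_rate = as.integer(sample_rate),
                 clip_duration = clip_duration,
                 segment_duration = segment_duration,
                 segment_overlap = segment_overlap,
                 n_mels = as.integer(n_mels),
                 win_length = as.integer(win_length),
                 hop_length = as.integer(hop_length),
                 log_floor = log_floor,
                 mel_scale = mel_scale,
                 center = center),
            class = "frontend_config")
}

# Frames produced by the centered STFT of one analysis segment.
segment_frames <- function(config) {
  n <- as.integer(round(config$segment_duration * config$sample_rate))
  if (config$center) 1L + n %/% config$hop_length
  else max(1L, 1L + (n - config$win_length) %/% config$hop_length)
}

#' Construct a labeled mono audio clip
#'
#' @param samples numeric vector of amplitudes in `[-1, 1]`
#' @param rate sample rate in Hz
#' @param label optional class id from [class_dictionary()]
#' @param source_id identifier of the parent recording
#' @param segment_index optional 1-based index of the analysis segment
#'   within its parent clip
#' @param augmentation optional `list(rate =, semitones =)` descriptor
#' @return object of class `audio_clip`
#' @export
audio_clip <- function(samples, rate, label = NULL, source_id = "clip",
                       segment_index = NULL, augmentation = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("audio clip must contain at least one sample")
  if (!all(is.finite(samples))) stop("audio clip contains non-finite samples")
  if (!is.null(label) && !label %in% class_dictionary())
    stop("unknown class label: ", label)
  structure(list(samples = samples, rate = as.integer(rate), label = label,
                 source_id = source_id, segment_index = segment_index,
                 augmentation = augmentation),
            class = "audio_clip")
}

#' @export
print.audio_clip <- function(x, ...) {
  cat(sprintf("<audio_clip> %s: %.3f s @ %d Hz%s%s\n", x$source_id,
              length(x$samples) / x$rate, x$rate,
              if (!is.null(x$label)) paste0(", label=", x$label) else "",
              if (!is.null(x$augmentation))
                sprintf(", aug(rate=%.2f, shift=%+d)", x$augmentation$rate,
                        x$augmentation$semitones) else ""))
  invisible(x)
}

clip_duration <- function(clip) length(clip$samples) / clip$rate

#' Load an audio file as a standardized mono clip
#'
#' Reads a RIFF/WAV file, averages channels to mono, resamples to the
#' configured rate with a polyphase rational resampler, and rescales if the
#' peak exceeds full scale.
#'
#' @param path path to a WAV file
#' @param label optional class id
#' @param source_id recording identifier; defaults to the file name
#' @param config a [frontend_config()]
#' @return an [audio_clip()] at `config$sample_rate`
#' @export
load_clip <- function(path, label = NULL, source_id = NULL,
                      config = frontend_config()) {
  wav <- read_wav(path)
  x <- colMeans(wav$samples)
  x <- resample_to(x, wav$rate, config$sample_rate)
  peak <- max(abs(x))
  if (peak > 1) x <- x / peak
  audio_clip(x, config$sample_rate, label = label,
             source_id = source_id %||% basename(path))
}

# Rational polyphase resampling from `from` Hz to `to` Hz.
resample_to <- function(x, from, to) {
  if (from == to) return(x)
  g <- gcd(as.integer(from), as.integer(to))
  p <- as.integer(to) %/% g
  q <- as.integer(from) %/% g
  as.numeric(signal::resample(x, p, q))
}

gcd <- function(a, b) if (b == 0L) a else gcd(b, a %% b)

#' Standardize a clip to the nominal duration by trailing zero-padding
#'
#' Clips shorter than the configured duration (2 s) are zero-padded at the
#' tail; clips at or above it are passed through unchanged and left to the
#' sliding-window segmentation.
#'
#' @param clip an [audio_clip()]
#' @param config a [frontend_config()]
#' @return an [audio_clip()] of at least `config$clip_duration` seconds
#' @export
standardize_duration <- function(clip, config = frontend_config()) {
  target <- as.integer(round(config$clip_duration * clip$rate))
  n <- length(clip$samples)
  if (n >= target) return(clip)
  out <- clip
  out$samples <- c(clip$samples, numeric(target - n))
  out
}

#' Split a clip into overlapping 1-second analysis segments
#'
#' Windows of `segment_duration` seconds are tiled with 50% overlap; if the
#' full windows do not cover the tail of the clip, one final window is
#' zero-padded to full length. Segment indices are recorded in provenance.
#'
#' @param clip an [audio_clip()] of at least `segment_duration` seconds
#' @param config a [frontend_config()]
#' @return list of [audio_clip()] segments, each of exactly
#'   `segment_duration` seconds
#' @export
segment_clip <- function(clip, config = frontend_config()) {
  seg <- as.integer(round(config$segment_duration * clip$rate))
  hop <- as.integer(round(seg * (1 - config$segment_overlap)))
  n <- length(clip$samples)
  if (n < seg) stop("clip shorter than one segment; standardize first")
  n_full <- 1L + (n - seg) %/% hop
  starts <- (seq_len(n_full) - 1L) * hop
  if (starts[n_full] + seg < n) starts <- c(starts, n_full * hop)
  lapply(seq_along(starts), function(i) {
    s <- starts[i]
    x <- clip$samples[(s + 1L):min(s + seg, n)]
    if (length(x) < seg) x <- c(x, numeric(seg - length(x)))
    audio_clip(x, clip$rate, label = clip$label, source_id = clip$source_id,
               segment_index = i, augmentation = clip$augmentation)
  })
}

#' Extract the log-Mel spectrogram of a 1-second segment
#'
#' Magnitude STFT (1024-sample window, 512-sample hop, centered frames),
#' squared to power, pooled by a 128-band triangular mel filterbank spanning
#' 0 to Nyquist, and log-compressed with an additive floor. A 1-s segment at
#' 22050 Hz yields a 128 x 44 matrix.
#'
#' @param segment an [audio_clip()] of exactly `segment_duration` seconds
#' @param config a [frontend_config()]
#' @return object of class `logmel_spectrogram` with fields `values`
#'   (n_mels x n_frames), `config`, and `provenance`
#' @export
extract_logmel <- function(segment, config = frontend_config()) {
  expected <- as.integer(round(config$segment_duration * config$sample_rate))
  if (length(segment$samples) != expected)
    stop("segment must contain exactly ", expected, " samples, got ",
         length(segment$samples))
  if (segment$rate != config$sample_rate)
    stop("segment rate does not match configuration")
  sp <- stft(segment$samples, config$win_length, config$hop_length,
             config$center)
  power <- Mod(sp)^2
  fb <- mel_filterbank(config$n_mels, config$win_length, config$sample_rate,
                       scale = config$mel_scale)
  values <- log(fb %*% power + config$log_floor)
  structure(list(values = values, config = config,
                 provenance = list(source_id = segment$source_id,
                                   segment_index = segment$segment_index,
                                   label = segment$label,
                                   augmentation = segment$augmentation)),
            class = "logmel_spectrogram")
}

#' @export
print.logmel_spectrogram <- function(x, ...) {
  cat(sprintf("<logmel_spectrogram> %d x %d (%s, segment %s)\n",
              nrow(x$values), ncol(x$values),
              x$provenance$source_id %||% "?",
              x$provenance$segment_index %||% "?"))
  invisible(x)
}

#' Read a corpus manifest
#'
#' A manifest is a CSV with columns `path`, `label`, `source_id` pointing at
#' per-clip WAV files.
#'
#' @param path CSV file path
#' @return data.frame with the three manifest columns
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("path", "label", "source_id")
  if (!all(req %in% names(m)))
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  m
}

#' Full frontend chain for one clip
#'
#' Standardizes the clip's duration, segments it, and extracts one log-Mel
#' spectrogram per segment.
#'
#' @param clip an [audio_clip()]
#' @param config a [frontend_config()]
#' @return list of `logmel_spectrogram` objects
#' @export
clip_logmels <- function(clip, config = frontend_config()) {
  clip <- standardize_duration(clip, config)
  lapply(segment_clip(clip, config), extract_logmel, config = config)
}
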