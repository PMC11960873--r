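#' Time-stretch / pitch-shift augmentation grid
#'
#' The training-time augmentation protocol: every 1-s segment is rendered at
#' three tempo rates (0.8, 1.0, 1.2) and, for each, five pitch shifts (-2 to
#' +2 semitones), giving 15 variants including the identity pair.
#'
#' @param stretch_rates ordered vector of tempo rates
#' @param semitone_shifts ordered vector of integer semitone shifts
#' @return object of class `augmentation_grid`
#' @export
augmentation_grid <- function(stretch_rates = c(0.8, 1.0, 1.2),
                              semitone_shifts = -2:2) {
  stopifnot(all(stretch_rates > 0), all(abs(semitone_shifts) <= 12))
  structure(list(stretch_rates = stretch_rates,
                 semitone_shifts = as.integer(semitone_shifts)),
            class = "augmentation_grid")
}

#' The identity-only augmentation grid
#'
#' A degenerate grid containing only the (1.0, 0) pair, used when training
#' should see original segments only (e.g. quick desk-scale experiments).
#'
#' @return an [augmentation_grid()] with a single identity cell
#' @export
identity_grid <- function() augmentation_grid(1.0, 0L)

grid_size <- function(grid) length(grid$stretch_rates) * length(grid$semitone_shifts)

# Classic phase vocoder: resample the STFT frame sequence at `rate` steps
# while accumulating per-bin phase so that instantaneous frequencies are
# preserved.
phase_vocoder <- function(spec, rate, hop = 512L, n_fft = 1024L) {
  n_bins <- nrow(spec)
  n_frames <- ncol(spec)
  steps <- seq(0, n_frames - 1, by = rate)
  phi_adv <- 2 * pi * (0:(n_bins - 1L)) * hop / n_fft # expected advance/hop
  out <- matrix(complex(real = 0), n_bins, length(steps))
  phase <- Arg(spec[, 1L])
  mag0 <- Mod(spec)
  for (k in seq_along(steps)) {
    p <- steps[k]
    i0 <- min(floor(p) + 1, n_frames)
    i1 <- min(i0 + 1L, n_frames)
    frac <- p - (i0 - 1L)
    mag <- (1 - frac) * mag0[, i0] + frac * mag0[, i1]
    out[, k] <- mag * exp(1i * phase)
    dphi <- Arg(spec[, i1]) - Arg(spec[, i0]) - phi_adv
    dphi <- dphi - 2 * pi * round(dphi / (2 * pi)) # wrap to (-pi, pi]
    phase <- phase + phi_adv + dphi
  }
  out
}

#' Time-stretch a segment (phase vocoder)
#'
#' Changes duration by `1/rate` while preserving pitch: output length is
#' exactly `round(n / rate)` samples.
#'
#' @param segment an [audio_clip()]
#' @param rate tempo rate (> 0); 0.8 slows down, 1.2 speeds up
#' @param config a [frontend_config()] supplying the STFT parameters
#' @return an [audio_clip()] of `round(n / rate)` samples
#' @export
time_stretch <- function(segment, rate, config = frontend_config()) {
  if (!is.numeric(rate) || length(rate) != 1L || rate <= 0)
    stop("stretch rate must be a positive number")
  out <- segment
  if (rate != 1) {
    sp <- stft(segment$samples, config$win_length, config$hop_length)
    sps <- phase_vocoder(sp, rate, config$hop_length, config$win_length)
    out$samples <- istft(sps, config$win_length, config$hop_length,
                         length = as.integer(round(length(segment$samples) / rate)))
  }
  out
}

#' Pitch-shift a segment
#'
#' Scales all frequencies by `2^(semitones/12)` while preserving duration:
#' a phase-vocoder stretch by the reciprocal factor followed by rational
#' resampling back to the original length.
#'
#' @param segment an [audio_clip()]
#' @param semitones integer shift in `[-12, 12]`
#' @param config a [frontend_config()]
#' @return an [audio_clip()] of the same length as the input
#' @export
pitch_shift <- function(segment, semitones, config = frontend_config()) {
  if (!is.numeric(semitones) || length(semitones) != 1L || abs(semitones) > 12)
    stop("semitone shift must lie in [-12, 12]")
  if (semitones == 0) return(segment)
  f <- 2^(semitones / 12)
  n <- length(segment$samples)
  stretched <- time_stretch(segment, 1 / f, config) # length n * f, same pitch
  pq <- best_rational(1 / f, max_den = 1024L)
  y <- as.numeric(signal::resample(stretched$samples, pq[1L], pq[2L]))
  if (length(y) >= n) y <- y[seq_len(n)] else y <- c(y, numeric(n - length(y)))
  out <- segment
  out$samples <- y
  out
}

# Best rational approximation p/q to `x` with denominator at most max_den.
best_rational <- function(x, max_den = 1024L) {
  q <- seq_len(max_den)
  p <- round(q * x)
  err <- abs(p / q - x)
  i <- which.min(err)
  c(as.integer(p[i]), as.integer(q[i]))
}

#' Generate all augmentation variants of a 1-second segment
#'
#' For each stretch rate the result is refitted to exactly one second
#' (tail-trimmed or zero-padded), then each semitone shift is applied.
#' Variants are emitted in rate-major, shift-minor order and carry their
#' `(rate, semitones)` descriptor; label and source_id are inherited.
#'
#' @param segment a 1-second [audio_clip()]
#' @param grid an [augmentation_grid()]
#' @param config a [frontend_config()]
#' @return list of `length(rates) * length(shifts)` segments, each of
#'   exactly `segment_duration` seconds
#' @export
augment_segment <- function(segment, grid = augmentation_grid(),
                            config = frontend_config()) {
  n <- as.integer(round(config$segment_duration * config$sample_rate))
  if (length(segment$samples) != n)
    stop("augment_segment expects a 1-second segment (", n, " samples)")
  out <- vector("list", grid_size(grid))
  i <- 0L
  for (rate in grid$stretch_rates) {
    st <- time_stretch(segment, rate, config)
    if (length(st$samples) >= n) st$samples <- st$samples[seq_len(n)]
    else st$samples <- c(st$samples, numeric(n - length(st$samples)))
    for (s in grid$semitone_shifts) {
      v <- pitch_shift(st, s, config)
      v$augmentation <- list(rate = rate, semitones = as.integer(s))
      i <- i + 1L
      out[[i]] <- v
    }
  }
  out
}
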