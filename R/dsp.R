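# Core short-time Fourier machinery shared by the frontend, the
# phase-vocoder augmentation and the sonification code.

# Periodic Hann window (matches the usual analysis-window convention for
# 50%-overlap STFT processing).
hann_window <- function(n) 0.5 - 0.5 * cos(2 * pi * (0:(n - 1)) / n)

#' Short-time Fourier transform
#'
#' Centered framing: frame `k` (0-based) is centered on sample `k * hop`,
#' the signal being zero-padded by `win/2` on both sides, which gives
#' `1 + floor(n / hop)` frames.
#'
#' @param x numeric signal
#' @param win window length in samples
#' @param hop hop size in samples
#' @param center center frames on `k * hop` (default) rather than starting
#'   them there
#' @return complex matrix `(win/2 + 1) x n_frames`
#' @export
stft <- function(x, win = 1024L, hop = 512L, center = TRUE) {
  n <- length(x)
  if (center) {
    n_frames <- 1L + n %/% hop
    pad <- win %/% 2L
    xp <- c(numeric(pad), x, numeric(max(0L, (n_frames - 1L) * hop + win - n - pad)))
  } else {
    n_frames <- max(1L, 1L + (n - win) %/% hop)
    xp <- c(x, numeric(max(0L, (n_frames - 1L) * hop + win - n)))
  }
  starts <- (seq_len(n_frames) - 1L) * hop
  frames <- vapply(starts, function(s) xp[(s + 1L):(s + win)], numeric(win))
  frames <- frames * hann_window(win)
  sp <- stats::mvfft(frames)
  sp[seq_len(win %/% 2L + 1L), , drop = FALSE]
}

#' Inverse short-time Fourier transform
#'
#' Window-weighted overlap-add with squared-window normalization, the
#' inverse of [stft()] for centered frames.
#'
#' @param spec complex matrix `(win/2 + 1) x n_frames`
#' @param win,hop,center as in [stft()]
#' @param length target output length in samples; the natural overlap-add
#'   length is trimmed or zero-padded to it when given
#' @return numeric signal
#' @export
istft <- function(spec, win = 1024L, hop = 512L, center = TRUE, length = NULL) {
  n_bins <- nrow(spec)
  n_frames <- ncol(spec)
  stopifnot(n_bins == win %/% 2L + 1L)
  full <- rbind(spec, Conj(spec[(n_bins - 1L):2L, , drop = FALSE]))
  frames <- Re(stats::mvfft(full, inverse = TRUE)) / win
  w <- hann_window(win)
  total <- (n_frames - 1L) * hop + win
  y <- numeric(total)
  wsum <- numeric(total)
  for (k in seq_len(n_frames)) {
    idx <- ((k - 1L) * hop + 1L):((k - 1L) * hop + win)
    y[idx] <- y[idx] + frames[, k] * w
    wsum[idx] <- wsum[idx] + w * w
  }
  nz <- wsum > 1e-10
  y[nz] <- y[nz] / wsum[nz]
  if (center) y <- y[(win %/% 2L + 1L):total]
  if (!is.null(length)) {
    if (base::length(y) >= length) y <- y[seq_len(length)]
    else y <- c(y, numeric(length - base::length(y)))
  }
  y
}

hz_to_mel <- function(f, scale = c("slaney", "htk")) {
  scale <- match.arg(scale)
  if (scale == "htk") return(2595 * log10(1 + f / 700))
  # Slaney: linear below 1 kHz, logarithmic above
  m <- f / (200 / 3)
  logstep <- log(6.4) / 27
  hi <- f >= 1000
  m[hi] <- 15 + log(f[hi] / 1000) / logstep
  m
}

mel_to_hz <- function(m, scale = c("slaney", "htk")) {
  scale <- match.arg(scale)
  if (scale == "htk") return(700 * (10^(m / 2595) - 1))
  f <- m * (200 / 3)
  logstep <- log(6.4) / 27
  hi <- m >= 15
  f[hi] <- 1000 * exp(logstep * (m[hi] - 15))
  f
}

#' Triangular mel filterbank
#'
#' @param n_mels number of mel bands
#' @param n_fft FFT size (filters are defined on `n_fft/2 + 1` bins)
#' @param rate sample rate in Hz
#' @param fmin,fmax frequency range covered by the bank
#' @param scale mel scale variant, `"slaney"` (default) or `"htk"`
#' @return `n_mels x (n_fft/2 + 1)` matrix with attribute
#'   `"center_freqs"` (Hz) holding each band's center frequency
#' @export
mel_filterbank <- function(n_mels = 128L, n_fft = 1024L, rate = 22050,
                           fmin = 0, fmax = rate / 2,
                           scale = c("slaney", "htk")) {
  scale <- match.arg(scale)
  pts <- mel_to_hz(seq(hz_to_mel(fmin, scale), hz_to_mel(fmax, scale),
                       length.out = n_mels + 2L), scale)
  bin_freqs <- (0:(n_fft %/% 2L)) * rate / n_fft
  fb <- matrix(0, n_mels, n_fft %/% 2L + 1L)
  for (m in seq_len(n_mels)) {
    lower <- (bin_freqs - pts[m]) / max(pts[m + 1L] - pts[m], 1e-12)
    upper <- (pts[m + 2L] - bin_freqs) / max(pts[m + 2L] - pts[m + 1L], 1e-12)
    fb[m, ] <- pmax(0, pmin(lower, upper))
  }
  attr(fb, "center_freqs") <- pts[2:(n_mels + 1L)]
  fb
}
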