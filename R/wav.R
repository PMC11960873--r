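#' Read a RIFF/WAV PCM file
#'
#' Minimal WAV reader covering the encodings found in field-recording
#' corpora: unsigned 8-bit, signed 16/24/32-bit integer PCM and 32/64-bit
#' IEEE float, mono or multi-channel, including WAVE_FORMAT_EXTENSIBLE
#' headers. Samples are returned as doubles in `[-1, 1]`.
#'
#' @param path path to a `.wav` file
#' @return list with `samples` (channels x n matrix) and `rate` (Hz)
#' @export
read_wav <- function(path) {
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 44) stop("unreadable or empty WAV file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  if (!identical(readChar(con, 4L, useBytes = TRUE), "RIFF"))
    stop("not a RIFF/WAV file: ", path)
  readBin(con, "integer", 1L, 4L, endian = "little")
  if (!identical(readChar(con, 4L, useBytes = TRUE), "WAVE"))
    stop("not a RIFF/WAV file: ", path)

  fmt <- NULL
  data_raw <- NULL
  repeat {
    id <- readChar(con, 4L, useBytes = TRUE)
    if (length(id) == 0L || nchar(id, type = "bytes") < 4L) break
    len <- readBin(con, "integer", 1L, 4L, endian = "little")
    if (length(len) == 0L) break
    if (identical(id, "fmt ")) {
      fmt <- readBin(con, "raw", len)
    } else if (identical(id, "data")) {
      data_raw <- readBin(con, "raw", len)
    } else {
      readBin(con, "raw", len)
    }
    if (len %% 2L == 1L) readBin(con, "raw", 1L) # chunk pad byte
  }
  if (is.null(fmt)) stop("WAV file has no fmt chunk: ", path)
  if (is.null(data_raw) || length(data_raw) == 0L)
    stop("WAV file has no audio samples: ", path)

  u16 <- function(raw, off) {
    b <- as.integer(raw[off + 1:2]); b[1] + 256L * b[2]
  }
  u32 <- function(raw, off) {
    b <- as.numeric(as.integer(raw[off + 1:4]))
    b[1] + 256 * b[2] + 65536 * b[3] + 16777216 * b[4]
  }
  audio_format <- u16(fmt, 0L)
  n_channels <- u16(fmt, 2L)
  rate <- u32(fmt, 4L)
  bits <- u16(fmt, 14L)
  if (audio_format == 65534L && length(fmt) >= 26L) { # extensible: subformat
    audio_format <- u16(fmt, 24L)
  }
  is_float <- audio_format == 3L
  if (!audio_format %in% c(1L, 3L))
    stop("unsupported WAV encoding (format tag ", audio_format, "): ", path)

  n_bytes <- bits %/% 8L
  n_total <- length(data_raw) %/% n_bytes
  x <- if (is_float) {
    readBin(data_raw, "numeric", n_total, size = n_bytes, endian = "little")
  } else if (bits == 8L) {
    (readBin(data_raw, "integer", n_total, size = 1L, signed = FALSE) - 128) / 128
  } else if (bits == 16L) {
    readBin(data_raw, "integer", n_total, size = 2L, signed = TRUE,
            endian = "little") / 32768
  } else if (bits == 24L) {
    b <- matrix(as.numeric(as.integer(data_raw[seq_len(n_total * 3L)])),
                nrow = 3L)
    v <- b[1, ] + 256 * b[2, ] + 65536 * b[3, ]
    v[v >= 8388608] <- v[v >= 8388608] - 16777216
    v / 8388608
  } else if (bits == 32L) {
    readBin(data_raw, "integer", n_total, size = 4L, signed = TRUE,
            endian = "little") / 2147483648
  } else {
    stop("unsupported PCM bit depth (", bits, "): ", path)
  }
  n_frames <- length(x) %/% n_channels
  if (n_frames < 1L) stop("WAV file has no audio samples: ", path)
  samples <- matrix(x[seq_len(n_frames * n_channels)], nrow = n_channels)
  list(samples = samples, rate = rate)
}

#' Write a mono or multi-channel WAV file (16-bit PCM)
#'
#' @param samples numeric vector (mono) or channels x n matrix in `[-1, 1]`
#' @param rate sample rate in Hz
#' @param path output path
#' @return `path`, invisibly
#' @export
write_wav <- function(samples, rate, path) {
  if (is.null(dim(samples))) samples <- matrix(samples, nrow = 1L)
  samples <- pmax(pmin(samples, 1), -1)
  pcm <- as.integer(round(samples * 32767))
  n_channels <- nrow(samples)
  data_len <- length(pcm) * 2L
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36L + data_len), con, size = 4L, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(16L, con, size = 4L, endian = "little")
  writeBin(1L, con, size = 2L, endian = "little")           # PCM
  writeBin(n_channels, con, size = 2L, endian = "little")
  writeBin(as.integer(rate), con, size = 4L, endian = "little")
  writeBin(as.integer(rate * n_channels * 2L), con, size = 4L,
           endian = "little")                                # byte rate
  writeBin(as.integer(n_channels * 2L), con, size = 2L, endian = "little")
  writeBin(16L, con, size = 2L, endian = "little")           # bits
  writeChar("data", con, eos = NULL)
  writeBin(data_len, con, size = 4L, endian = "little")
  writeBin(pcm, con, size = 2L, endian = "little")
  invisible(path)
}
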