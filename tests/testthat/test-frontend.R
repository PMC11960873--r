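test_that("WAV ingest standardizes channels, rate and peak", {
  # identity: mono file already at the target rate
  x <- sin(2 * pi * 440 * (0:22049) / 22050) * 0.5
  f <- tempfile(fileext = ".wav")
  write_wav(x, 22050, f)
  clip <- load_clip(f)
  expect_s3_class(clip, "audio_clip")
  expect_equal(clip$rate, 22050L)
  expect_equal(length(clip$samples), 22050L)
  expect_gt(cor(clip$samples, x), 0.999)

  # stereo 44100 Hz: channel mean then 2:1 rational resample
  st <- rbind(x, x * 0.5)
  f2 <- tempfile(fileext = ".wav")
  write_wav(st, 44100, f2)
  clip2 <- load_clip(f2)
  expect_equal(length(clip2$samples), 11025L) # 22050 samples at half rate
  expect_true(all(abs(clip2$samples) <= 1))

  # degenerate input
  f3 <- tempfile(fileext = ".wav")
  file.create(f3)
  expect_error(load_clip(f3), "unreadable|empty")
})

test_that("duration standardization zero-pads short clips only", {
  short <- audio_clip(rnorm(15435) / 10, 22050)
  out <- standardize_duration(short)
  expect_equal(length(out$samples), 44100L)
  expect_true(all(out$samples[15436:44100] == 0))

  exact <- audio_clip(rnorm(44100) / 10, 22050)
  expect_identical(standardize_duration(exact)$samples, exact$samples)

  long <- audio_clip(rnorm(66150) / 10, 22050)
  expect_identical(standardize_duration(long)$samples, long$samples)
})

test_that("segmentation tiles 1-s windows with 50% overlap", {
  clip <- audio_clip(rnorm(44100) / 10, 22050, label = "heat",
                     source_id = "rec1")
  segs <- segment_clip(clip)
  expect_length(segs, 3L)
  for (i in 1:3) {
    start <- (i - 1L) * 11025L
    expect_identical(segs[[i]]$samples,
                     clip$samples[(start + 1):(start + 22050)])
    expect_equal(segs[[i]]$segment_index, i)
    expect_equal(segs[[i]]$label, "heat")
    expect_equal(segs[[i]]$source_id, "rec1")
  }

  one <- audio_clip(rnorm(22050) / 10, 22050)
  expect_length(segment_clip(one), 1L)
  expect_identical(segment_clip(one)[[1]]$samples, one$samples)

  # 2.3 s: three full windows leave an uncovered tail -> one padded window
  odd <- audio_clip(rnorm(50715) / 10, 22050)
  segs_odd <- segment_clip(odd)
  expect_length(segs_odd, 4L)
  expect_equal(length(segs_odd[[4]]$samples), 22050L)
  expect_true(all(segs_odd[[4]]$samples[(50715 - 33075 + 1):22050] == 0))

  expect_length(segment_clip(audio_clip(rnorm(55125) / 10, 22050)), 4L)
})

test_that("log-mel extraction has the contracted shape and floor", {
  silence <- audio_clip(numeric(22050), 22050)
  lm <- extract_logmel(silence)
  expect_equal(dim(lm$values), c(128L, 44L))
  expect_true(all(abs(lm$values - log(1e-10)) < 1e-12))

  tone <- tone_segment(1000)
  lt <- extract_logmel(tone)
  expect_equal(dim(lt$values), c(128L, 44L))
  fb <- mel_filterbank()
  nearest <- which.min(abs(attr(fb, "center_freqs") - 1000))
  expect_equal(which.max(rowMeans(lt$values)), nearest)

  expect_error(extract_logmel(audio_clip(numeric(1000), 22050)),
               "exactly")
})

test_that("centered framing yields 1 + floor(n/hop) frames", {
  for (n in c(11025L, 22050L, 44100L)) {
    expect_equal(ncol(stft(numeric(n))), 1L + n %/% 512L)
  }
})

test_that("amplitude scaling never decreases log-mel cells above the floor", {
  seg <- generate_call(default_specs()$heat, seed = 21)
  seg <- segment_clip(standardize_duration(seg))[[1]]
  a <- extract_logmel(seg)$values
  seg2 <- seg
  seg2$samples <- seg$samples * 1.8
  b <- extract_logmel(seg2)$values
  expect_true(all(b >= a - 1e-12))
})

test_that("extraction is deterministic for identical input bytes", {
  seg <- tone_segment(700)
  expect_identical(extract_logmel(seg)$values, extract_logmel(seg)$values)
})

test_that("manifests round-trip through CSV", {
  d <- tempfile()
  dir.create(d)
  specs <- tiny_specs()
  corpus <- generate_corpus(stats::setNames(c(2L, 2L, 2L), names(specs)),
                            seed = 5, specs = specs)
  mf <- write_corpus(corpus, d)
  m <- read_manifest(mf)
  expect_equal(nrow(m), 6L)
  expect_setequal(unique(m$label), names(specs))
  clip <- load_clip(m$path[1], label = m$label[1], source_id = m$source_id[1])
  expect_equal(length(clip$samples), 44100L)
  ref <- corpus$clips[[1]]
  expect_gt(cor(clip$samples, ref$samples), 0.999) # 16-bit quantization only
})
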