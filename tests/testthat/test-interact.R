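test_that("region masks threshold positive relevance at a percentile", {
  h <- matrix(0, 128, 44)
  h[64, 22] <- 5
  m <- region_mask(h, p = 90)
  expect_equal(m$mask[64, 22], 1)
  expect_equal(sum(m$mask), 1)
  # p = 0 covers every positive-relevance cell
  h2 <- matrix(rnorm(128 * 44), 128, 44)
  m2 <- region_mask(h2, p = 0)
  expect_equal(sum(m2$mask), sum(h2 > 0))
  # extents bracket the selected cell
  ext <- mask_extents(m)
  expect_equal(ext$time[1], ext$time[2])
  expect_equal(ext$time[1], 21 * 512 / 22050)
  fb <- mel_filterbank()
  expect_equal(ext$freq[1], attr(fb, "center_freqs")[64])
})

test_that("sonification inverts masked spectrogram regions", {
  call <- generate_call(default_specs()$heat, seed = 5)
  seg <- segment_clip(standardize_duration(call))[[1]]
  # transparent mask: near-perfect round trip
  rec <- sonify_region(seg, matrix(1, 128, 44))
  expect_equal(length(rec$samples), length(seg$samples))
  expect_gte(cor(rec$samples, seg$samples), 0.95)
  # opaque mask: digital silence
  mute <- sonify_region(seg, matrix(0, 128, 44))
  expect_lt(max(abs(mute$samples)), 1e-6)
  # band mask around a pure tone passes the tone through
  tone <- tone_segment(1000)
  cf <- attr(mel_filterbank(), "center_freqs")
  mask <- matrix(0, 128, 44)
  mask[abs(cf - 1000) < 150, ] <- 1
  filtered <- sonify_region(tone, mask)
  expect_lt(abs(peak_frequency(filtered) - 1000), 5)
  # energy bound: masking in [0,1] never adds energy
  set.seed(3)
  for (i in 1:3) {
    m <- matrix(runif(128 * 44), 128, 44)
    out <- sonify_region(seg, m)
    expect_lte(sqrt(mean(out$samples^2)), sqrt(mean(seg$samples^2)) * 1.01)
  }
  expect_error(sonify_region(seg, matrix(1, 64, 44)), "shape")
})

test_that("influence answers localize the discriminative band", {
  fit <- tiny_trained()
  spec <- tiny_specs()$social_isolation
  clip <- generate_call(spec, seed = 91, source_id = "probe")
  ans <- answer_influence(fit$net, clip, p = 90)
  expect_true(ans$class %in% fit$net$classes)
  expect_equal(dim(ans$heatmap), c(128L, 44L))
  expect_equal(length(ans$audio$samples), 22050L)
  if (identical(ans$class, "social_isolation")) {
    # reported frequency extent overlaps the true band
    expect_true(ans$extents$freq[1] <= spec$band[2] &&
                  ans$extents$freq[2] >= spec$band[1])
  }
})

test_that("cosine retrieval agrees with a brute-force oracle", {
  fit <- tiny_trained()
  E <- corpus_embeddings(fit$net, fit$corpus)
  expect_equal(ncol(E), length(fit$corpus$clips))
  query <- fit$corpus$clips[[5]]
  nb <- find_similar(fit$net, query, E, top_k = ncol(E))
  # the query itself comes first at distance ~0
  expect_equal(nb$id[1], query$source_id)
  expect_lt(nb$distance[1], 1e-9)
  # full ranking matches an exhaustive sort
  q <- rowMeans(embed(fit$net, bleatr:::clip_logmels(query)))
  d_manual <- apply(E, 2, function(e)
    1 - sum(e * q) / (sqrt(sum(e^2)) * sqrt(sum(q^2))))
  expect_equal(nb$id, colnames(E)[order(d_manual)])
  expect_equal(nb$distance, unname(sort(d_manual)), tolerance = 1e-12)
  # distances live in [0,1] for non-negative (post-ReLU) embeddings
  expect_true(all(nb$distance >= -1e-12 & nb$distance <= 1))
  # dissimilar is the reverse ordering of the same distances
  far <- find_dissimilar(fit$net, query, E, top_k = ncol(E))
  expect_equal(far$id, rev(nb$id))
  # permutation invariance of the corpus
  perm <- sample(ncol(E))
  nb2 <- find_similar(fit$net, query, E[, perm], top_k = 5L)
  expect_equal(nb2$id, nb$id[1:5])
  expect_error(find_similar(fit$net, query, E[, 0, drop = FALSE]), "empty")
})

test_that("relevance differences are antisymmetric and self-cancelling", {
  fit <- tiny_trained()
  a <- fit$corpus$clips[[1]]
  b <- fit$corpus$clips[[10]]
  self <- relevance_difference(fit$net, a, a, p = 90)
  expect_true(all(self$difference == 0))
  expect_equal(sum(self$mask$mask), 0)
  ab <- relevance_difference(fit$net, a, b, p = 90)
  ba <- relevance_difference(fit$net, b, a, p = 90)
  expect_equal(ab$difference, -ba$difference, tolerance = 1e-12)
  expect_equal(ab$mask$mask, ba$mask$mask, tolerance = 1e-12)
  expect_equal(length(ab$sonified$a$samples), 22050L)
  expect_equal(length(ab$sonified$b$samples), 22050L)
})
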