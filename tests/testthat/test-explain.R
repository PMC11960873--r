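test_that("epsilon-rule relevance matches the hand-computed linear case", {
  w <- c(0.5, -0.3, 1.2)
  x <- c(1, 2, 0.5)
  net <- dense_network(list(matrix(w, 1, 3)))
  b <- relevance(net, x, target = 1)
  # y = w.x; R_i = x_i w_i y / (y + eps) ~ x_i w_i
  expect_equal(b$heatmap, x * w, tolerance = 1e-4)
  expect_equal(sum(b$heatmap), b$score, tolerance = 1e-4)
})

test_that("zero input with zero biases yields an all-zero heatmap", {
  net <- small_cnn()
  x <- array(0, dim = c(32L, 16L, 1L, 1L))
  b <- relevance(net, x, 1)
  expect_true(all(b$heatmap == 0))
})

test_that("relevance is conserved through zero-bias dense stacks", {
  set.seed(42)
  for (rep in 1:5) {
    sizes <- sample(2:16, 4)
    net <- dense_network(list(
      matrix(rnorm(sizes[2] * sizes[1]), sizes[2], sizes[1]),
      matrix(rnorm(sizes[3] * sizes[2]), sizes[3], sizes[2]),
      matrix(rnorm(sizes[4] * sizes[3]), sizes[4], sizes[3])))
    x <- rnorm(sizes[1])
    target <- sample(sizes[4], 1)
    b <- relevance(net, x, target)
    if (abs(b$score) > 1e-3) {
      expect_lt(abs(sum(b$heatmap) - b$score) / abs(b$score), 1e-4)
    }
  }
})

test_that("a vacuous condition reproduces the unconditional heatmap", {
  net <- small_cnn()
  x <- small_input()
  un <- relevance(net, x, 3)
  all_ch <- relevance(net, x, 3,
                      conditions = list(conv3_1 = seq_len(8L)))
  expect_lt(max(abs(un$heatmap - all_ch$heatmap)), 1e-9)
})

test_that("conditions are validated against the network", {
  net <- small_cnn()
  x <- small_input()
  expect_error(relevance(net, x, 1, conditions = list(nope = 1L)),
               "unknown layer")
  expect_error(relevance(net, x, 1, conditions = list(conv1_1 = 99L)),
               "out of range")
})

test_that("singleton-channel heatmaps sum to the unconditional heatmap", {
  net <- small_cnn()
  x <- small_input()
  un <- relevance(net, x, 2)
  for (layer in c("conv2_1", "conv4_2", "fc1")) {
    width <- layer_width(net, layer)
    total <- 0
    for (ch in seq_len(width)) {
      total <- total +
        relevance(net, x, 2,
                  conditions = stats::setNames(list(ch), layer))$heatmap
    }
    expect_lt(max(abs(total - un$heatmap)) / max(abs(un$heatmap)), 1e-6)
  }
})

test_that("channel rankings order by summed relevance with additivity", {
  net <- small_cnn()
  x <- small_input()
  rk <- rank_channels(net, x, 2, "conv3_2")
  expect_s3_class(rk, "channel_ranking")
  expect_true(all(diff(rk$score) <= 1e-12))
  # additivity: channel scores sum to the total layer relevance
  bundle <- relevance(net, x, 2)
  tens <- bundle$layer_relevance[["conv3_2"]]
  expect_equal(sum(rk$score), sum(tens), tolerance = 1e-9)
  # relevance concentrated in one channel ranks it first
  masked <- relevance(net, x, 2,
                      conditions = list(conv3_2 = 5L))
  expect_equal(which(apply(masked$layer_relevance$conv3_2, 3,
                           function(s) sum(abs(s))) > 0), 5L)
})

test_that("sample reports render top-k conditional heatmaps per layer", {
  net <- small_cnn()
  x <- small_input()
  rep <- sample_report(net, x, 2, layers = c("conv4_2"), k = 6L)
  expect_length(rep$conv4_2$heatmaps, 6L)
  expect_true(all(diff(rep$conv4_2$scores) <= 1e-12))
  # k equal to the layer width decomposes the unconditional heatmap
  width <- layer_width(net, "conv4_2")
  full <- sample_report(net, x, 2, layers = "conv4_2", k = width)
  un <- relevance(net, x, 2)$heatmap
  expect_equal(Reduce(`+`, full$conv4_2$heatmaps), un, tolerance = 1e-8)
  # degenerate and out-of-range k
  empty <- sample_report(net, x, 2, layers = "conv4_2", k = 0L)
  expect_length(empty$conv4_2$heatmaps, 0L)
  expect_error(sample_report(net, x, 2, layers = "conv4_2", k = width + 1L),
               "exceeds")
})

test_that("central-sample selection matches a brute-force distance sort", {
  set.seed(7)
  base <- matrix(rnorm(128 * 44), 128, 44)
  near <- lapply(1:4, function(i)
    as_logmel(base + 0.01 * matrix(rnorm(128 * 44), 128, 44)))
  outlier <- as_logmel(base + 5)
  sel <- select_central(c(near[1:2], list(outlier)), 2L)
  expect_setequal(sel$indices, c(1L, 2L))
  # n equal to class size returns everything
  all3 <- select_central(c(near[1:2], list(outlier)), 3L)
  expect_setequal(all3$indices, 1:3)
  expect_error(select_central(near[1], 2L), "cannot select")
  # duplicating a non-selected outlier still never selects it
  sel2 <- select_central(c(near, list(outlier, outlier)), 2L)
  expect_true(all(sel2$indices <= 4L))
})

test_that("class-average heatmaps count their contributors", {
  net <- small_cnn()
  set.seed(13)
  specs <- lapply(1:4, function(i)
    as_logmel(matrix(rnorm(32 * 16), 32, 16)))
  # bypass shape checks: small net input is 32 x 16
  ch <- class_average_heatmap(net, specs, 2L, n = 4L, g = 2L,
                              layers = c("conv2_2", "conv4_1", "fc1"))
  expect_equal(ch$contributors, 24L)
  expect_equal(ch$mbar, 8L * 4L * 2L)
  expect_equal(dim(ch$heatmap), c(32L, 16L))
  # n = 1, g = 1, one layer: the average is that single conditional map
  one <- class_average_heatmap(net, specs[1], 2L, n = 1L, g = 1L,
                               layers = "conv4_1")
  rk <- rank_channels(net, specs[[1]], 2L, "conv4_1")
  single <- relevance(net, specs[[1]], 2L,
                      conditions = list(conv4_1 = rk$channel[1]))$heatmap
  expect_equal(one$heatmap, single)
  # idempotence under duplicated identical samples
  two <- class_average_heatmap(net, specs[c(1, 1)], 2L, n = 2L, g = 1L,
                               layers = "conv4_1")
  expect_equal(two$heatmap, single, tolerance = 1e-12)
})
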