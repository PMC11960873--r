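test_that("the architecture spec enforces the published topology", {
  spec <- architecture_spec()
  expect_equal(spec$eff_filters, c(64L, 128L, 256L, 512L))
  expect_equal(spec$eff_dense, 4096L)
  expect_equal(spec$n_classes, 8L)
  # full-width conv stack: (64,64,128,128,256,256,512,512)
  expect_equal(rep(spec$eff_filters, each = spec$convs_per_block),
               c(64L, 64L, 128L, 128L, 256L, 256L, 512L, 512L))
  # width multiplier scales filters and dense units jointly
  spec8 <- architecture_spec(width_multiplier = 0.125)
  expect_equal(spec8$eff_filters, c(8L, 16L, 32L, 64L))
  expect_equal(spec8$eff_dense, 512L)
  # input must survive all pooling stages
  expect_error(architecture_spec(input_shape = c(8L, 4L, 1L)), "small")
})

test_that("network construction is seeded and has the derivable size", {
  spec <- architecture_spec(width_multiplier = 0.125)
  net <- build_network(spec, seed = 1)
  net2 <- build_network(spec, seed = 1)
  expect_identical(bleatr:::get_params(net), bleatr:::get_params(net2))
  net3 <- build_network(spec, seed = 2)
  expect_false(identical(bleatr:::get_params(net), bleatr:::get_params(net3)))

  # layer-by-layer parameter arithmetic
  f <- spec$eff_filters
  d <- spec$eff_dense
  cin <- c(1L, f[1], f[1], f[2], f[2], f[3], f[3], f[4])
  cout <- rep(f, each = 2L)
  conv_params <- sum(9L * cin * cout + cout)
  # after 4 poolings: 128x44 -> 8x2, flattened with f[4] channels
  dense_params <- (8L * 2L * f[4]) * d + d + d * d + d + d * 8L + 8L
  expect_equal(count_parameters(net), conv_params + dense_params)

  # pooled spatial map before flatten is 8 x 2
  flat <- Filter(function(l) l$type == "flatten", net$layers)[[1]]
  expect_equal(flat$in_dim[1:2], c(8L, 2L))
})

test_that("forward returns softmax rows over the 8 classes", {
  net <- build_network(architecture_spec(width_multiplier = 0.125), seed = 4)
  set.seed(8)
  x <- array(rnorm(128 * 44 * 3), dim = c(128L, 44L, 1L, 3L))
  p <- predict_proba(net, x)
  expect_equal(dim(p), c(3L, 8L))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  expect_equal(colnames(p), class_dictionary())
  # duplicated inputs give identical rows (deterministic inference)
  x2 <- x
  x2[, , , 2] <- x[, , , 1]
  p2 <- predict_proba(net, x2)
  expect_equal(p2[1, ], p2[2, ])
})

test_that("embeddings are the width-scaled second dense activation", {
  spec <- architecture_spec(width_multiplier = 0.125)
  net <- build_network(spec, seed = 4)
  expect_equal(architecture_spec()$eff_dense, 4096L) # nominal width
  silence <- as_logmel(matrix(log(1e-10), 128, 44))
  e <- embed(net, silence)
  expect_length(e, 512L)
  expect_true(all(is.finite(e)))
  expect_identical(e, embed(net, silence))
})

test_that("checkpoints round-trip through disk", {
  net <- small_cnn()
  f <- tempfile(fileext = ".rds")
  save_network(net, f)
  expect_true(file.exists(sub("\\.rds$", "_spec.json", f)))
  net2 <- load_network(f)
  x <- small_input()
  expect_identical(bleatr:::forward_pass(net, x)$logits,
                   bleatr:::forward_pass(net2, x)$logits)
})

test_that("backpropagation gradients match finite differences", {
  net <- small_cnn(seed = 3)
  set.seed(10)
  x <- array(rnorm(32 * 16 * 2), dim = c(32L, 16L, 1L, 2L))
  y <- c(2L, 5L)
  lossfn <- function(n) {
    bleatr:::cross_entropy(bleatr:::forward_pass(n, x)$probs, y)
  }
  fw <- bleatr:::forward_pass(net, x, keep_cache = TRUE)
  dl <- t(fw$probs)
  dl[cbind(y, 1:2)] <- dl[cbind(y, 1:2)] - 1
  dl <- dl / 2
  grads <- bleatr:::backward_pass(net, fw$cache, dl)
  params <- bleatr:::get_params(net)
  eps <- 1e-6
  set.seed(11)
  for (li in c(1L, 4L, 9L, 11L)) {
    for (fld in c("W", "b")) {
      p <- params[[li]][[fld]]
      for (t in sample(length(p), min(4L, length(p)))) {
        p2 <- params
        p2[[li]][[fld]][t] <- p[t] + eps
        lp <- lossfn(bleatr:::set_params(net, p2))
        p2[[li]][[fld]][t] <- p[t] - eps
        lm <- lossfn(bleatr:::set_params(net, p2))
        fd <- (lp - lm) / (2 * eps)
        an <- grads[[li]][[fld]][t]
        expect_lt(abs(fd - an), 1e-5 * max(1, abs(fd)))
      }
    }
  }
})
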