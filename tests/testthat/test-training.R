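make_source_manifest <- function(n_per_class, classes = class_dictionary()) {
  do.call(rbind, lapply(classes, function(cl) {
    data.frame(source_id = sprintf("%s_%03d", cl, seq_len(n_per_class)),
               label = cl, stringsAsFactors = FALSE)
  }))
}

test_that("stratified folds partition sources with at most one-sample skew", {
  m <- make_source_manifest(40L)
  plan <- make_folds(m, k = 5L, seed = 3L)
  a <- plan$assignments
  # partition: every source exactly once
  expect_setequal(a$source_id, m$source_id)
  expect_equal(anyDuplicated(a$source_id), 0L)
  # exact divisibility: 8 sources per class per fold
  expect_true(all(table(a$label, a$fold) == 8L))
  # determinism
  plan2 <- make_folds(m, k = 5L, seed = 3L)
  expect_identical(plan$assignments, plan2$assignments)
  plan3 <- make_folds(m, k = 5L, seed = 4L)
  expect_false(identical(plan$assignments, plan3$assignments))
})

test_that("fold construction rejects degenerate requests by name", {
  m <- make_source_manifest(40L)
  expect_error(make_folds(m, k = 1L), "at least 2")
  m2 <- rbind(make_source_manifest(40L, "heat"),
              make_source_manifest(3L, "parturition"))
  expect_error(make_folds(m2, k = 5L, seed = 1L), "parturition")
  expect_error(make_folds(make_source_manifest(10L, "heat"), k = 2L),
               "two classes")
})

test_that("imbalanced corpora keep per-fold proportions within one sample", {
  m <- rbind(make_source_manifest(33L, "heat"),
             make_source_manifest(7L, "social_isolation"),
             make_source_manifest(12L, "parturition"))
  plan <- make_folds(m, k = 5L, seed = 9L)
  tab <- table(plan$assignments$label, plan$assignments$fold)
  for (cl in rownames(tab)) {
    expect_lte(diff(range(tab[cl, ])), 1L)
  }
})

test_that("no source leaks between augmented training data and test folds", {
  corpus <- tiny_corpus()
  plan <- make_folds(corpus$manifest, k = 2L, seed = 11L)
  for (fold in 1:2) {
    train_ids <- bleatr:::fold_sources(plan, fold, "train")
    test_ids <- bleatr:::fold_sources(plan, fold, "test")
    expect_length(intersect(train_ids, test_ids), 0L)
    # the augmented feature set carries only training sources
    feats <- bleatr:::corpus_features(corpus, train_ids,
                                      grid = identity_grid())
    expect_length(intersect(unique(feats$source_ids), test_ids), 0L)
  }
})

test_that("training with max_epochs = 0 returns the initialized network", {
  corpus <- tiny_corpus()
  plan <- make_folds(corpus$manifest, k = 2L, seed = 11L)
  cfg <- train_config(max_epochs = 0L, k_folds = 2L, seed = 11L)
  fit <- train_fold(corpus, plan, 1L, tiny_arch(), cfg, identity_grid())
  expect_equal(nrow(fit$history), 0L)
  ref <- build_network(bleatr:::architecture_spec(
    block_filters = c(4L, 6L, 8L, 8L), dense_units = 32L, n_classes = 3L),
    seed = derive_seed(11L, 501L))
  expect_identical(count_parameters(fit$net), count_parameters(ref))
})

test_that("separable synthetic data is learned to perfect training accuracy", {
  fit <- tiny_trained()
  expect_equal(max(fit$history$train_acc), 1.0)
})

test_that("full-batch training loss decreases monotonically without dropout", {
  corpus <- tiny_corpus()
  plan <- make_folds(corpus$manifest, k = 2L, seed = 11L)
  arch <- architecture_spec(block_filters = c(4L, 6L, 8L, 8L),
                            dense_units = 32L, dropout_rate = 0)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 36L,
                      max_epochs = 8L, early_stopping = NULL,
                      validation_fraction = 0, k_folds = 2L, seed = 11L)
  fit <- train_fold(corpus, plan, 1L, arch, cfg, identity_grid())
  expect_true(all(diff(fit$history$train_loss) <= 1e-3))
})

test_that("training is deterministic under a fixed seed", {
  corpus <- tiny_corpus()
  plan <- make_folds(corpus$manifest, k = 2L, seed = 11L)
  cfg <- train_config(learning_rate = 1e-3, batch_size = 8L, max_epochs = 2L,
                      early_stopping = NULL, validation_fraction = 0,
                      k_folds = 2L, seed = 11L)
  f1 <- train_fold(corpus, plan, 1L, tiny_arch(), cfg, identity_grid())
  f2 <- train_fold(corpus, plan, 1L, tiny_arch(), cfg, identity_grid())
  expect_identical(f1$history, f2$history)
})

test_that("evaluation aggregates segments and rejects augmented test clips", {
  fit <- tiny_trained()
  test_ids <- bleatr:::fold_sources(fit$plan, 1L, "test")
  rep <- evaluate(fit$net, fit$corpus, test_ids)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(unname(rowSums(rep$rates)[rowSums(rep$confusion) > 0]),
               rep(1, 3), tolerance = 1e-9)
  expect_gte(rep$mean_recall, 2 / 3) # three well-separated classes
  # clip-level prediction is the argmax of mean segment softmax
  clip <- fit$corpus$clips[[match(test_ids[1],
                                  fit$corpus$manifest$source_id)]]
  probs <- predict_proba(fit$net, bleatr:::clip_logmels(clip))
  manual <- fit$net$classes[which.max(colMeans(probs))]
  expect_equal(unname(rep$confusion[clip$label, manual]) >= 1, TRUE)

  corrupted <- fit$corpus
  poison <- match(test_ids[1], corrupted$manifest$source_id)
  corrupted$clips[[poison]]$augmentation <- list(rate = 0.8, semitones = 1L)
  expect_error(evaluate(fit$net, corrupted, test_ids), "augmented")
})

test_that("a trained model tolerates one-hop time shifts of its input", {
  fit <- tiny_trained()
  test_ids <- bleatr:::fold_sources(fit$plan, 1L, "test")
  flips <- 0L
  total <- 0L
  for (sid in test_ids) {
    clip <- fit$corpus$clips[[match(sid, fit$corpus$manifest$source_id)]]
    shifted <- clip
    shifted$samples <- c(numeric(512), clip$samples[1:(44100 - 512)])
    p1 <- colMeans(predict_proba(fit$net, bleatr:::clip_logmels(clip)))
    p2 <- colMeans(predict_proba(fit$net, bleatr:::clip_logmels(shifted)))
    flips <- flips + (which.max(p1) != which.max(p2))
    total <- total + 1L
  }
  expect_lt(flips / total, 0.1)
})
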