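test_that("inverse class frequency weights follow N/(K*n_c)", {
  ## balanced classes get unit weight
  expect_equal(unname(compute_class_weights(c(a = 100, b = 100))), c(1, 1))
  ## the weighted-count identity holds for arbitrary count vectors
  set.seed(1)
  for (i in 1:20) {
    counts <- sample(1:5000, sample(2:6, 1))
    w <- compute_class_weights(counts)
    expect_equal(sum(counts * w), sum(counts))
  }
  expect_error(compute_class_weights(c(a = 0, b = 10)), "count >= 1")
})

test_that("stratified split preserves class proportions and is deterministic", {
  y <- factor(rep(c("a", "b"), times = c(60, 40)))
  sp <- stratified_split(y, 0.8, seed = 5)
  expect_equal(sum(y[sp$train] == "a"), 48)
  expect_equal(sum(y[sp$train] == "b"), 32)
  expect_equal(length(sp$validation), 20)
  expect_setequal(c(sp$train, sp$validation), seq_along(y))
  ## same seed, same partition
  expect_identical(sp, stratified_split(y, 0.8, seed = 5))
  ## adversarial ordering: all of one class first
  y2 <- factor(c(rep("a", 30), rep("b", 10)))
  sp2 <- stratified_split(y2, 0.8, seed = 6)
  expect_equal(sum(y2[sp2$train] == "a"), 24)
  expect_equal(sum(y2[sp2$train] == "b"), 8)
  expect_error(stratified_split(factor(c("a", "b", "b")), 0.8, 1), ">= 2")
})

test_that("the CNN separates a linearly separable toy set perfectly", {
  toy <- toy_trace_set(n = 200, input_length = 400, seed = 9)
  sp <- stratified_split(toy$labels, 0.8, seed = 10)
  cfg <- model_config(conv_blocks = list(c(9, 8)), pool = 8, dense = 16,
                      n_classes = 2, input_length = 400, max_epochs = 6,
                      seed = 11)
  fit <- train_cnn(toy$x[sp$train, ], toy$labels[sp$train], cfg,
                   validation = list(x = toy$x[sp$validation, ],
                                     y = toy$labels[sp$validation]))
  expect_equal(fit$metrics$accuracy, 1.0)
  expect_equal(fit$metrics$macro_f1, 1.0)
})

test_that("training is reproducible and prediction is batch-invariant", {
  toy <- toy_trace_set(n = 80, input_length = 200, seed = 12)
  cfg <- model_config(conv_blocks = list(c(9, 8)), pool = 8, dense = 16,
                      n_classes = 2, input_length = 200, max_epochs = 20,
                      batch_size = 8, seed = 13)
  f1 <- train_cnn(toy$x, toy$labels, cfg)
  f2 <- train_cnn(toy$x, toy$labels, cfg)
  expect_equal(f1$params, f2$params, tolerance = 1e-12)
  expect_equal(f1$metrics$accuracy, f2$metrics$accuracy, tolerance = 1e-4)
  ## batch vs single-trace prediction agree
  pb <- predict(f1, toy$x)
  ps <- vapply(1:10, function(i) as.character(predict(f1, toy$x[i, ])), "")
  expect_equal(as.character(pb[1:10]), ps)
  ## memorization: an overfit model reproduces its training labels
  expect_gte(mean(as.character(pb) == as.character(toy$labels)), 0.99)
  ## pad/truncate policy is applied and flagged
  expect_warning(pshort <- predict(f1, toy$x[1:2, 1:150]), "adjusted")
  expect_equal(length(pshort), 2)
})

test_that("shuffled labels drive validation accuracy to chance", {
  toy <- toy_trace_set(n = 200, input_length = 200, seed = 14)
  sp <- stratified_split(toy$labels, 0.8, seed = 15)
  cfg <- model_config(conv_blocks = list(c(5, 4)), pool = 8, dense = 8,
                      n_classes = 2, input_length = 200, max_epochs = 4,
                      seed = 16)
  y_perm <- with(list(), { set.seed(17); sample(toy$labels) })
  fit <- train_cnn(toy$x[sp$train, ], y_perm[sp$train], cfg,
                   validation = list(x = toy$x[sp$validation, ],
                                     y = y_perm[sp$validation]))
  ## balanced two-class problem: chance is 0.5; allow 5 points
  expect_lt(abs(fit$metrics$accuracy - 0.5), 0.05 + 1e-9)
})

test_that("cross-validation folds partition the data and report per-fold metrics", {
  toy <- toy_trace_set(n = 100, input_length = 200, seed = 18)
  cfg <- model_config(conv_blocks = list(c(9, 8)), pool = 8, dense = 16,
                      n_classes = 2, input_length = 200, max_epochs = 20,
                      batch_size = 8, seed = 19)
  cv <- cross_validate(toy$x, toy$labels, cfg, k = 5, seed = 20)
  expect_equal(nrow(cv$folds), 5)
  expect_equal(sum(cv$folds$n_validation), 100)
  ## folds are disjoint and exhaustive
  expect_setequal(cv$fold_assignment, 1:5)
  expect_equal(length(cv$fold_assignment), 100)
  ## stratification: per-fold class counts within 1 of n/k per class
  for (f in 1:5) {
    tab <- table(toy$labels[cv$fold_assignment == f])
    expect_true(all(abs(tab - 10) <= 1))
  }
  ## separable set: perfect mean accuracy
  expect_equal(cv$mean_accuracy, 1.0)
  expect_equal(cv$sd_accuracy, 0)
  expect_error(cross_validate(toy$x[1:8, ], toy$labels[1:8], cfg, k = 5, 1),
               "5-fold")
})

test_that("architecture search ranks configurations and picks by CV accuracy", {
  toy <- toy_trace_set(n = 150, input_length = 200, seed = 21)
  good <- model_config(conv_blocks = list(c(9, 8)), pool = 8, dense = 16,
                       n_classes = 2, input_length = 200, max_epochs = 4)
  ## degenerate candidate: single 1-filter block and a crippled learning rate
  bad <- model_config(conv_blocks = list(c(3, 1)), pool = 50, dense = 2,
                      n_classes = 2, input_length = 200, max_epochs = 1,
                      learning_rate = 1e-7)
  res <- architecture_search(toy$x, toy$labels, list(bad, good), seed = 22,
                             top_k = 2, cv_k = 3)
  expect_equal(res$ranking$config[1], 2)   # the known-good config ranks first
  expect_equal(res$best_index, 2)
  ## a grid of one: that config wins
  res1 <- architecture_search(toy$x, toy$labels, list(good), seed = 23,
                              top_k = 1, cv_k = 3)
  expect_equal(res1$best_index, 1)
  ## the default demonstration grid spans 39 architectures
  expect_length(default_search_grid(), 39)
})

test_that("a trained CNN round-trips through JSON serialization", {
  toy <- toy_trace_set(n = 60, input_length = 200, seed = 24)
  cfg <- model_config(conv_blocks = list(c(5, 4)), pool = 8, dense = 8,
                      n_classes = 2, input_length = 200, max_epochs = 2,
                      seed = 25)
  fit <- train_cnn(toy$x, toy$labels, cfg)
  path <- tempfile(fileext = ".json")
  save_cnn(fit, path)
  fit2 <- load_cnn(path)
  expect_equal(fit2$params, fit$params, tolerance = 1e-12)
  expect_identical(as.character(predict(fit2, toy$x)),
                   as.character(predict(fit, toy$x)))
})
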