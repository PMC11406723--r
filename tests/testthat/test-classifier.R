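test_that("forward pass matches a hand-rolled per-layer oracle", {
  cfg <- model_config(input_dim = 4L, n_classes = 3L, hidden_sizes = c(5L, 4L),
                      dropout_rate = 0, standardize = FALSE, seed = 7L,
                      epochs = 0L)
  set.seed(99)
  model <- train_mlp(matrix(rnorm(12), 3, 4), c("a", "b", "c"), cfg)
  X <- matrix(rnorm(8), 2, 4)
  out <- forward(model, X)
  # explicit loops, independent of the vectorized implementation
  oracle <- matrix(0, 2, 3)
  for (r in 1:2) {
    h <- X[r, ]
    for (l in 1:2) {
      z <- as.vector(h %*% model$layers[[l]]$W) + model$layers[[l]]$b
      h <- ifelse(z > 0, z, 0)
    }
    z <- as.vector(h %*% model$layers[[3]]$W) + model$layers[[3]]$b
    oracle[r, ] <- 1 / (1 + exp(-z))
  }
  expect_equal(out, oracle, tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(all(out > 0 & out < 1))
})

test_that("zero weights score 0.5 everywhere and ties resolve by class order", {
  cfg <- model_config(input_dim = 3L, n_classes = 4L, hidden_sizes = c(4L, 4L),
                      standardize = FALSE, epochs = 0L, seed = 1L)
  model <- train_mlp(matrix(rnorm(12), 4, 3), c("w", "x", "y", "z"), cfg)
  model$layers <- lapply(model$layers, function(l) {
    list(W = l$W * 0, b = l$b * 0)
  })
  out <- forward(model, matrix(rnorm(6), 2, 3))
  expect_equal(out, matrix(0.5, 2, 4), ignore_attr = TRUE)
  expect_equal(predict(model, matrix(rnorm(6), 2, 3)), c("w", "w"))
})

test_that("dropout 0 makes train- and eval-mode passes identical", {
  cfg <- model_config(input_dim = 5L, n_classes = 2L, dropout_rate = 0,
                      epochs = 0L, standardize = FALSE, seed = 3L)
  model <- train_mlp(matrix(rnorm(10), 2, 5), c("a", "b"), cfg)
  X <- matrix(rnorm(20), 4, 5)
  expect_identical(forward(model, X, train_mode = TRUE),
                   forward(model, X, train_mode = FALSE))
})

test_that("averaged train-mode passes approximate the eval-mode pass (inverted dropout)", {
  cfg <- model_config(input_dim = 3L, n_classes = 2L, hidden_sizes = c(6L, 4L),
                      dropout_rate = 0.3, epochs = 0L, standardize = FALSE,
                      seed = 5L)
  model <- train_mlp(matrix(rnorm(9), 3, 3), c("a", "b", "a"), cfg)
  model$layers <- lapply(model$layers, function(l) {
    list(W = l$W * 0.5, b = l$b)           # mild weights keep the map near-linear
  })
  X <- matrix(rnorm(6), 2, 3)
  eval_out <- forward(model, X, train_mode = FALSE)
  set.seed(123)
  acc <- matrix(0, 2, 2)
  for (i in 1:10000) acc <- acc + forward(model, X, train_mode = TRUE)
  expect_equal(acc / 10000, eval_out, tolerance = 0.05)
})

test_that("training fits a linearly separable embedding and is fully seeded", {
  fix <- separable_embedding(100, seed = 0)
  cfg <- model_config(input_dim = 5L, n_classes = 2L, seed = 0L)
  m1 <- train_mlp(fix$X, fix$y, cfg)
  expect_gte(accuracy(fix$y, predict(m1, fix$X)), 0.99)
  expect_gte(mean(predict(m1, fix$X) == fix$y), 0.99)
  # loss decreased from its initial value
  expect_lt(m1$history$train_loss[nrow(m1$history)], m1$history$train_loss[1])

  m2 <- train_mlp(fix$X, fix$y, cfg)
  expect_identical(m1$layers, m2$layers)   # determinism under seeding

  cfg0 <- model_config(input_dim = 5L, n_classes = 2L, epochs = 0L, seed = 0L)
  m0a <- train_mlp(fix$X, fix$y, cfg0)
  m0b <- train_mlp(fix$X, fix$y, cfg0)
  expect_identical(m0a$layers, m0b$layers) # untouched initialization
  expect_equal(nrow(m0a$history), 0L)
})

test_that("training rejects degenerate inputs", {
  X <- matrix(rnorm(20), 10, 2)
  expect_error(train_mlp(X, rep("a", 10),
                         model_config(2L, 2L)), "at least 2 classes")
  expect_error(train_mlp(X, rep(c("a", "b"), 5),
                         model_config(3L, 2L)), "input_dim")
})

test_that("a serialized model reproduces predictions bit-exactly", {
  fix <- separable_embedding(30, seed = 2)
  model <- train_mlp(fix$X, fix$y, fast_config(5L, 2L, seed = 2L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)
  X <- fix$X[c(3, 40, 55), ]
  expect_identical(predict_proba(back, X), predict_proba(model, X))
  expect_identical(predict(back, X), predict(model, X))
})

test_that("the softmax loss variant trains and scores sum to one", {
  fix <- separable_embedding(40, seed = 3)
  cfg <- fast_config(5L, 2L, loss = "softmax_ce", seed = 3L)
  model <- train_mlp(fix$X, fix$y, cfg)
  s <- predict_proba(model, fix$X[1:5, ])
  expect_equal(unname(rowSums(s)), rep(1, 5), tolerance = 1e-9)
  expect_gte(accuracy(fix$y, predict(model, fix$X)), 0.95)
})

test_that("dropout_sweep returns one evaluated row per rate", {
  fix <- separable_embedding(40, seed = 4)
  cfg <- fast_config(5L, 2L, seed = 4L)
  tab1 <- dropout_sweep(fix$X, fix$y, rates = 0, config = cfg)
  expect_equal(nrow(tab1), 1L)
  tab <- dropout_sweep(fix$X, fix$y, rates = c(0, 0.5), config = cfg)
  expect_equal(tab$rate, c(0, 0.5))
  expect_true(all(tab$acc >= 0 & tab$acc <= 1))
  expect_true(all(is.finite(tab$ari)) && all(is.finite(tab$nmi)))
})
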