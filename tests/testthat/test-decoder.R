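nd <- asNamespace("nirsdecode")

test_that("analytic gradients match finite differences for every architecture", {
  set.seed(71)
  spec <- model_spec(n_filters = 4, hidden_units = 3, n_classes = 2,
                     input_channels = 5, time_steps = 7, dropout_p = 0)
  N <- 6
  X <- array(rnorm(N * 5 * 7), c(N, 5, 7))
  y <- sample(1:2, N, replace = TRUE)
  for (kind in c("cnn_lstm", "cnn_only", "lstm_only", "cnn_lstm_seq")) {
    params <- nd$nn_init_params(kind, spec)
    loss_of <- function(p) {
      nd$softmax_xent(nd$nn_forward(kind, p, X, spec, train = FALSE)$logits,
                      y)$loss
    }
    cache <- nd$nn_forward(kind, params, X, spec, train = FALSE)
    sx <- nd$softmax_xent(cache$logits, y)
    g <- nd$nn_backward(kind, params, X, cache, sx$dlogits)
    for (nm in names(params)) {
      for (i in seq_len(min(length(params[[nm]]), 5))) {
        eps <- 1e-5
        p2 <- params; p2[[nm]][i] <- p2[[nm]][i] + eps; up <- loss_of(p2)
        p2[[nm]][i] <- p2[[nm]][i] - 2 * eps; dn <- loss_of(p2)
        num <- (up - dn) / (2 * eps)
        expect_lt(abs(num - g[[nm]][i]),
                  1e-4 * max(1, abs(num)))
      }
    }
  }
})

test_that("the forward pass honours the shape contract", {
  model <- build_cnn_lstm(model_spec(), seed = 1)
  X <- array(rnorm(8 * 38 * 405), c(8, 38, 405))
  logits <- predict(model, X, type = "logits")
  expect_equal(dim(logits), c(8L, 2L))
  # evaluation mode is deterministic despite the dropout layer
  expect_identical(predict(model, X), predict(model, X))
  # all-zero input flows through the bias pathway only
  z <- predict(model, array(0, c(4, 38, 405)), type = "logits")
  expect_equal(z[1, ], z[3, ])
  # wrong time length is a shape error
  expect_error(predict(model, array(0, c(2, 38, 100))), "405")
  expect_error(build_cnn_lstm(model_spec(), kind = "transformer"), "kind")
})

test_that("the default network stays desk-scale (< 1e6 parameters)", {
  for (kind in c("cnn_lstm", "cnn_only", "lstm_only")) {
    model <- build_cnn_lstm(model_spec(), kind = kind, seed = 1)
    expect_lt(nd$n_params(model$params), 1e6)
  }
})

test_that("early stopping obeys its patience contract", {
  samples <- separable_samples(6, n_ch = 6, n_t = 20, seed = 3)
  spec <- model_spec(n_filters = 4, hidden_units = 3, input_channels = 6,
                     time_steps = 20)
  arr <- nd$samples_to_array(samples)
  model <- build_cnn_lstm(spec, seed = 1)
  cfg <- train_config(learning_rate = 0, max_epochs = 50, patience = 1,
                      batch_size = 4, seed = 1)
  fit <- train_with_early_stopping(model, arr$X, arr$y, arr$X, arr$y, cfg)
  expect_equal(nrow(fit$history), 2L)   # epoch 1 sets the best, epoch 2 stops
})

test_that("separable classes are learned to perfection, permuted labels are not", {
  samples <- separable_samples(12, n_ch = 10, n_t = 30, seed = 5)
  spec <- model_spec(n_filters = 8, hidden_units = 6, input_channels = 10,
                     time_steps = 30)
  arr <- nd$samples_to_array(samples)
  cfg <- train_config(learning_rate = 1e-2, max_epochs = 200, patience = 20,
                      batch_size = 8, seed = 2)
  model <- build_cnn_lstm(spec, seed = 2)
  fit <- train_with_early_stopping(model, arr$X, arr$y, arr$X, arr$y, cfg)
  expect_equal(mean(predict(fit, arr$X) == arr$y), 1)
  # training reproduces bit-identically under the same seed
  fit2 <- train_with_early_stopping(build_cnn_lstm(spec, seed = 2),
                                    arr$X, arr$y, arr$X, arr$y, cfg)
  expect_identical(fit$params, fit2$params)
  # label permutation: held-out accuracy within the binomial null band
  set.seed(6)
  yperm <- sample(arr$y)
  half <- seq_len(12)
  hold <- setdiff(seq_len(24), half)
  fitp <- train_with_early_stopping(build_cnn_lstm(spec, seed = 3),
                                    arr$X[half, , , drop = FALSE], yperm[half],
                                    arr$X[hold, , , drop = FALSE], yperm[hold],
                                    train_config(learning_rate = 1e-2, max_epochs = 60,
                                                 patience = 10, batch_size = 8,
                                                 seed = 3))
  acc <- mean(predict(fitp, arr$X[hold, , , drop = FALSE]) == yperm[hold])
  expect_lt(abs(acc - 0.5), 2.58 * sqrt(0.25 / length(hold)) + 1e-9)
})

test_that("cross-validation runs one test evaluation per fold and a stub oracle checks out", {
  samples <- separable_samples(15, n_ch = 6, n_t = 20, seed = 8)
  split <- split_and_fold(samples, seed = 1, grouping = "sample")
  spec <- model_spec(n_filters = 4, hidden_units = 3, input_channels = 6,
                     time_steps = 20)
  cfg <- train_config(learning_rate = 1e-2, max_epochs = 40, patience = 8,
                      batch_size = 8, seed = 4)
  m <- crossvalidate_and_test(samples, split, spec, cfg)
  expect_equal(nrow(m), 5L)
  expect_equal(attr(m, "summary")$model, "cnn_lstm")
  expect_true(all(m$accuracy >= 0 & m$accuracy <= 1))
  # majority-class stub: constant predictions score exactly the prevalence
  y_test <- samples$label[split$test_idx]
  stub <- suppressWarnings(compute_metrics(y_test, rep(0L, length(y_test))))
  expect_equal(stub$accuracy, mean(y_test == 0))
})

test_that("baselines share the metrics schema", {
  samples <- separable_samples(15, n_ch = 6, n_t = 20, seed = 9)
  split <- split_and_fold(samples, seed = 2, grouping = "sample")
  spec <- model_spec(n_filters = 4, hidden_units = 3, input_channels = 6,
                     time_steps = 20)
  cfg <- train_config(learning_rate = 1e-2, max_epochs = 30, patience = 8,
                      batch_size = 8, seed = 5)
  cols <- c("model", "task", "fold", "accuracy", "recall", "precision", "f1")
  for (kind in c("svm", "cnn_only", "lstm_only")) {
    m <- train_baseline(kind, samples, split, spec, cfg)
    expect_named(as.data.frame(m), cols)
    expect_equal(nrow(m), 5L)
  }
  expect_error(train_baseline("forest", samples, split, spec, cfg), "forest")
})

test_that("the pool-after-LSTM ablation variant trains end to end", {
  # this variant optimises slowly (max-pool over recurrent states); give it
  # a hot learning rate and room to converge
  samples <- separable_samples(10, n_ch = 6, n_t = 20, noise_sd = 0.02,
                               seed = 10)
  spec <- model_spec(n_filters = 8, hidden_units = 8, input_channels = 6,
                     time_steps = 20, pool_after_lstm = TRUE)
  arr <- nd$samples_to_array(samples)
  model <- build_cnn_lstm(spec, seed = 1)
  expect_equal(model$kind, "cnn_lstm_seq")
  fit <- train_with_early_stopping(model, arr$X, arr$y, arr$X, arr$y,
                                   train_config(learning_rate = 3e-2,
                                                max_epochs = 400,
                                                patience = 399,
                                                batch_size = 20, seed = 1))
  expect_gte(mean(predict(fit, arr$X) == arr$y), 0.9)
})
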