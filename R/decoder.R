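#' CNN-LSTM architecture specification
#'
#' The hybrid decoder stacks: input (38 channels x 405 time steps), a Conv1D
#' layer with 1-wide kernels (stride 1, no padding) mixing the 38 channel
#' values at each time step into `n_filters` feature maps, a sigmoid, a
#' global max-pool whose kernel spans the full 405-step time axis, dropout
#' (p = 0.001), a single bidirectional LSTM layer, a ReLU, and a linear
#' read-out with 2 (or 3) units. The global pooling collapses time before
#' the LSTM, which therefore sees a length-1 sequence; this literal stacking
#' is the default, with a pool-after-LSTM variant available for ablation.
#'
#' @param n_filters Conv1D output feature maps (default 64).
#' @param hidden_units LSTM hidden units per direction (default 32).
#' @param dropout_p Dropout probability (default 0.001).
#' @param n_classes Output units, 2 for binary anger/happiness (default) or 3.
#' @param input_channels Input height (default 38 channels).
#' @param time_steps Pooling kernel = input time length (default 405).
#' @param pool_after_lstm If `TRUE`, use the ablation variant that runs the
#'   bidirectional LSTM over the full 405-step feature sequence and pools
#'   its hidden states over time afterwards.
#' @return An object of class `nirs_model_spec`.
#' @export
model_spec <- function(n_filters = 64L, hidden_units = 32L,
                       dropout_p = 0.001, n_classes = 2L,
                       input_channels = 38L, time_steps = 405L,
                       pool_after_lstm = FALSE) {
  if (dropout_p < 0 || dropout_p >= 1) abort("`dropout_p` must be in [0, 1).")
  if (!n_classes %in% c(2L, 3L)) abort("`n_classes` must be 2 or 3.")
  structure(list(n_filters = as.integer(n_filters),
                 hidden_units = as.integer(hidden_units),
                 dropout_p = dropout_p, n_classes = as.integer(n_classes),
                 input_channels = as.integer(input_channels),
                 time_steps = as.integer(time_steps),
                 pool_after_lstm = isTRUE(pool_after_lstm)),
            class = "nirs_model_spec")
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 1e-3; see
#'   [learning_rate_grid()] for the documented tuning grid).
#' @param max_epochs Maximum training epochs (default 500).
#' @param patience Early-stopping patience in epochs without validation
#'   improvement (default 25, the midpoint of the 20-30 range the protocol
#'   allows).
#' @param batch_size Minibatch size (default 16).
#' @param seed Seed controlling initialisation, shuffling and dropout.
#' @param k Cross-validation folds (default 5).
#' @return An object of class `nirs_train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, max_epochs = 500L,
                         patience = 25L, batch_size = 16L, seed = 1L,
                         k = 5L) {
  assert_scalar_number(learning_rate, "learning_rate")
  if (learning_rate < 0) abort("`learning_rate` must be >= 0.")
  if (patience >= max_epochs) abort("`patience` must be < `max_epochs`.")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed), k = as.integer(k)),
            class = "nirs_train_config")
}

#' The documented learning-rate tuning grid
#' @return Numeric vector `c(1e-2, 1e-3, 1e-4)`.
#' @export
learning_rate_grid <- function() c(1e-2, 1e-3, 1e-4)

#' Build a decoder model
#'
#' Instantiates the network of a given architecture with freshly initialised
#' parameters. `"cnn_lstm"` is the hybrid decoder of [model_spec()];
#' `"cnn_only"` keeps its convolution/pool front end plus the linear
#' read-out; `"lstm_only"` runs the bidirectional LSTM directly over the
#' (405-step, 38-feature) input sequence.
#'
#' @param spec An `nirs_model_spec`.
#' @param kind One of `"cnn_lstm"`, `"cnn_only"`, `"lstm_only"`.
#' @param seed Initialisation seed.
#' @return An object of class `nirs_decoder_model`.
#' @export
build_cnn_lstm <- function(spec = model_spec(), kind = "cnn_lstm", seed = 1L) {
  stopifnot(inherits(spec, "nirs_model_spec"))
  kind <- if (kind == "cnn_lstm" && spec$pool_after_lstm) "cnn_lstm_seq" else kind
  if (!kind %in% c("cnn_lstm", "cnn_lstm_seq", "cnn_only", "lstm_only")) {
    abort(sprintf("Unknown model kind '%s'.", kind))
  }
  params <- with_seed(seed, nn_init_params(kind, spec))
  structure(list(kind = kind, spec = spec, params = params),
            class = "nirs_decoder_model")
}

#' @export
print.nirs_decoder_model <- function(x, ...) {
  cat(sprintf("<nirs_decoder_model> %s: %d filters, %d hidden units/dir, %d classes, %d parameters\n",
              x$kind, x$spec$n_filters, x$spec$hidden_units,
              x$spec$n_classes, n_params(x$params)))
  invisible(x)
}

#' Forward pass returning class predictions
#'
#' Evaluation-mode forward (dropout disabled, hence deterministic).
#'
#' @param object An `nirs_decoder_model`.
#' @param newdata Array N x channels x time.
#' @param type `"class"` (0-based labels) or `"logits"`.
#' @param ... Unused.
#' @return Integer labels or a logit matrix.
#' @export
predict.nirs_decoder_model <- function(object, newdata,
                                       type = c("class", "logits"), ...) {
  type <- match.arg(type)
  cache <- nn_forward(object$kind, object$params, newdata, object$spec,
                      train = FALSE)
  if (type == "logits") return(cache$logits)
  max.col(cache$logits, ties.method = "first") - 1L
}

samples_to_array <- function(samples, idx = seq_len(nrow(samples))) {
  vals <- samples$values[idx]
  d <- dim(vals[[1]])
  X <- array(0, c(length(vals), d[1], d[2]))
  for (i in seq_along(vals)) X[i, , ] <- vals[[i]]
  list(X = X, y = as.integer(samples$label[idx]))
}

#' Train a decoder with validation-based early stopping
#'
#' Minimises the cross-entropy with Adam; after every epoch the validation
#' accuracy is evaluated, the best-epoch weights are retained, and training
#' stops once `patience` consecutive epochs bring no improvement (or at
#' `max_epochs`).
#'
#' @param model An `nirs_decoder_model`.
#' @param train_x,train_y Training array (N x C x T) and 0-based labels.
#' @param val_x,val_y Validation data, disjoint from training.
#' @param cfg An `nirs_train_config`.
#' @return The model with trained (best-epoch) parameters and a `history`
#'   tibble (epoch, train_loss, val_accuracy).
#' @export
train_with_early_stopping <- function(model, train_x, train_y, val_x, val_y,
                                      cfg = train_config()) {
  stopifnot(inherits(model, "nirs_decoder_model"),
            inherits(cfg, "nirs_train_config"))
  if (length(unique(train_y)) < 2) abort("Training data needs both classes.")
  n <- dim(train_x)[1]
  params <- model$params
  state <- adam_init(params)
  best <- list(acc = -Inf, params = params, epoch = 0L)
  streak <- 0L
  hist <- vector("list", cfg$max_epochs)
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      losses <- c()
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- train_x[idx, , , drop = FALSE]
        yb <- train_y[idx] + 1L
        cache <- nn_forward(model$kind, params, Xb, model$spec, train = TRUE)
        sx <- softmax_xent(cache$logits, yb)
        if (!is.finite(sx$loss)) {
          abort(sprintf("Training diverged (non-finite loss) at epoch %d.", epoch))
        }
        grads <- nn_backward(model$kind, params, Xb, cache, sx$dlogits)
        upd <- adam_step(params, grads, state, cfg$learning_rate)
        params <- upd$params; state <- upd$state
        losses <- c(losses, sx$loss)
      }
      val_pred <- {
        cache <- nn_forward(model$kind, params, val_x, model$spec, train = FALSE)
        max.col(cache$logits, ties.method = "first") - 1L
      }
      val_acc <- mean(val_pred == val_y)
      hist[[epoch]] <- tibble(epoch = epoch, train_loss = mean(losses),
                              val_accuracy = val_acc)
      if (val_acc > best$acc) {
        best <- list(acc = val_acc, params = params, epoch = epoch)
        streak <- 0L
      } else {
        streak <- streak + 1L
        if (streak >= cfg$patience) break
      }
    }
  })
  model$params <- best$params
  model$history <- dplyr::bind_rows(hist)
  model$best_epoch <- best$epoch
  model$best_val_accuracy <- best$acc
  model
}

fold_metrics_row <- function(y_true, y_pred, fold, model, task = NA_character_) {
  m <- compute_metrics(y_true, y_pred)
  tibble(model = model, task = task, fold = fold, accuracy = m$accuracy,
         recall = m$recall, precision = m$precision, f1 = m$f1)
}

#' Five-fold cross-validated training with a fixed test set
#'
#' For each fold, a fresh model is trained on the remaining training folds
#' with the held-out fold as the validation set for early stopping; the
#' best-epoch weights are then evaluated on the fixed test partition. The
#' reported metrics average the test evaluations of all `k` folds.
#'
#' @param samples An `nirs_contrast_samples` tibble.
#' @param split An `nirs_split_spec` from [split_and_fold()].
#' @param spec An `nirs_model_spec`.
#' @param cfg An `nirs_train_config`.
#' @param kind Model kind passed to [build_cnn_lstm()].
#' @return An object of class `nirs_metrics`: per-fold tibble with a
#'   `summary` attribute holding the means.
#' @export
crossvalidate_and_test <- function(samples, split, spec = model_spec(),
                                   cfg = train_config(), kind = "cnn_lstm") {
  stopifnot(inherits(split, "nirs_split_spec"))
  test <- samples_to_array(samples, split$test_idx)
  rows <- vector("list", split$k)
  fold_seeds <- derive_seeds(cfg$seed, split$k)
  for (j in seq_len(split$k)) {
    tr_idx <- split$train_idx[split$fold != j]
    va_idx <- split$train_idx[split$fold == j]
    tr <- samples_to_array(samples, tr_idx)
    va <- samples_to_array(samples, va_idx)
    cfg_j <- cfg; cfg_j$seed <- fold_seeds[j]
    model <- build_cnn_lstm(spec, kind = kind, seed = fold_seeds[j])
    model <- train_with_early_stopping(model, tr$X, tr$y, va$X, va$y, cfg_j)
    pred <- predict(model, test$X)
    rows[[j]] <- fold_metrics_row(test$y, pred, j, kind)
  }
  new_metrics(dplyr::bind_rows(rows))
}

new_metrics <- function(per_fold) {
  summary <- dplyr::summarise(
    dplyr::group_by(per_fold, .data$model),
    dplyr::across(c("accuracy", "recall", "precision", "f1"), mean),
    .groups = "drop")
  structure(per_fold, summary = summary,
            class = c("nirs_metrics", class(per_fold)))
}

#' @export
print.nirs_metrics <- function(x, ...) {
  cat("<nirs_metrics> mean over folds:\n")
  print(as.data.frame(attr(x, "summary")), row.names = FALSE)
  invisible(x)
}

#' Train a baseline classifier under the shared protocol
#'
#' Baselines follow exactly the cross-validation protocol of
#' [crossvalidate_and_test()]: `"svm"` fits a radial-kernel support vector
#' machine on per-channel mean features; `"cnn_only"` keeps the hybrid's
#' convolution/pool front end; `"lstm_only"` runs the bidirectional LSTM over
#' the full input sequence.
#'
#' @param kind `"svm"`, `"cnn_only"` or `"lstm_only"`.
#' @param svm_features `"channel_mean"` (default) collapses each channel to
#'   its temporal mean — the per-channel summary-feature convention shallow
#'   fNIRS classifiers typically use; `"flatten"` feeds the SVM the full
#'   vectorised 38 x 405 representation the networks see.
#' @inheritParams crossvalidate_and_test
#' @return An `nirs_metrics` object with the same schema as the hybrid's.
#' @export
train_baseline <- function(kind, samples, split, spec = model_spec(),
                           cfg = train_config(),
                           svm_features = c("channel_mean", "flatten")) {
  if (kind %in% c("cnn_only", "lstm_only")) {
    return(crossvalidate_and_test(samples, split, spec, cfg, kind = kind))
  }
  if (kind != "svm") {
    abort(sprintf("Unknown baseline '%s' (svm, cnn_only, lstm_only).", kind))
  }
  svm_features <- match.arg(svm_features)
  feats <- if (svm_features == "flatten") {
    t(vapply(samples$values, as.vector,
             numeric(length(samples$values[[1]]))))
  } else {
    t(vapply(samples$values, rowMeans,
             numeric(nrow(samples$values[[1]]))))
  }
  y <- as.integer(samples$label)
  test_i <- split$test_idx
  rows <- vector("list", split$k)
  for (j in seq_len(split$k)) {
    tr_idx <- split$train_idx[split$fold != j]
    fit <- e1071::svm(x = feats[tr_idx, , drop = FALSE],
                      y = factor(y[tr_idx], levels = sort(unique(y))),
                      kernel = "radial")
    pred <- as.integer(as.character(predict(fit, feats[test_i, , drop = FALSE])))
    rows[[j]] <- fold_metrics_row(y[test_i], pred, j, "svm")
  }
  new_metrics(dplyr::bind_rows(rows))
}
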