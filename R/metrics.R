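#' Classification metrics: accuracy, macro recall/precision, F1
#'
#' Accuracy is the fraction of correct predictions; precision and recall are
#' macro-averaged over the two classes; F1 is the harmonic mean
#' `2PR / (P + R)` of the macro precision and recall. A class absent from
#' the confusion table contributes 0 to its undefined ratio, with a warning.
#'
#' @param y_true,y_pred Equal-length label vectors over \{0, 1\}.
#' @return A one-row tibble with `accuracy`, `recall`, `precision`, `f1`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (!length(y_true)) abort("`y_true` is empty.")
  if (length(y_true) != length(y_pred)) {
    abort("`y_true` and `y_pred` must have equal length.")
  }
  classes <- sort(unique(c(y_true, y_pred)))
  if (!all(classes %in% c(0, 1))) abort("Labels must be 0 or 1.")
  classes <- c(0, 1)
  acc <- mean(y_true == y_pred)
  prec <- rec <- numeric(2)
  warned <- FALSE
  for (i in seq_along(classes)) {
    k <- classes[i]
    tp <- sum(y_true == k & y_pred == k)
    denom_p <- sum(y_pred == k)
    denom_r <- sum(y_true == k)
    if (denom_p == 0 || denom_r == 0) warned <- TRUE
    prec[i] <- if (denom_p == 0) 0 else tp / denom_p
    rec[i] <- if (denom_r == 0) 0 else tp / denom_r
  }
  if (warned) {
    warn("A class is absent from y_true or y_pred; its ratio was set to 0.")
  }
  P <- mean(prec); R <- mean(rec)
  f1 <- if (P + R == 0) 0 else 2 * P * R / (P + R)
  tibble(accuracy = acc, recall = R, precision = P, f1 = f1)
}
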