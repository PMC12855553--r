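#' Build a first-level design matrix
#'
#' One regressor per task condition — the condition boxcar convolved with the
#' canonical HRF, truncated to the recording length — plus a constant column.
#' Baseline fixation is the implicit reference and carries no regressor.
#'
#' @param design A `nirs_block_design` with at least one task condition.
#' @param hrf HRF kernel; default [canonical_hrf()] at the design's rate.
#' @param fs Sampling rate; defaults to the design's.
#' @return A numeric matrix (samples x regressors) of class
#'   `nirs_design_matrix` with attribute `task_regressors`.
#' @export
build_design_matrix <- function(design, hrf = canonical_hrf(design$fs),
                                fs = design$fs) {
  stopifnot(inherits(design, "nirs_block_design"))
  conds <- task_conditions(design)
  if (!length(conds)) abort("Design has no task condition.")
  n <- round(design$total_duration * fs)
  if (n <= 0) abort("Design has zero duration.")
  # unit-peak regressors: coefficients come out in peak-amplitude (uM) units
  X <- vapply(conds, function(cond) {
    condition_regressor(design, cond, hrf, n)
  }, numeric(n))
  X <- cbind(X, constant = 1)
  colnames(X) <- c(conds, "constant")
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1L):ncol(X)]]
    abort(sprintf("Design matrix is rank deficient; collinear regressor(s): %s",
                  paste(dropped, collapse = ", ")))
  }
  structure(X, task_regressors = conds, class = c("nirs_design_matrix", "matrix"))
}

#' Fit the channel-wise first-level GLM
#'
#' Per usable channel, the hemoglobin time series is pre-whitened together
#' with the design matrix under an AR(1) serial-correlation model
#' ([prewhiten_ar1()]), then fitted by ordinary least squares. Channels
#' marked unusable get missing coefficients and are excluded downstream.
#'
#' @param rec A preprocessed `nirs_recording` with hemoglobin planes.
#' @param X An `nirs_design_matrix`.
#' @param chromophore `"HbO"` or `"HbR"`.
#' @return An object of class `nirs_first_level` with per-channel
#'   coefficients, residual variance, degrees of freedom, AR(1) estimates and
#'   the whitened `(X'X)^-1` needed for contrast variances.
#' @export
fit_first_level <- function(rec, X, chromophore = "HbO") {
  stopifnot(inherits(rec, "nirs_recording"))
  plane <- match(chromophore, rec$planes)
  if (is.na(plane)) {
    abort(sprintf("Recording has no '%s' plane (has: %s).", chromophore,
                  paste(rec$planes, collapse = ", ")))
  }
  n <- dim(rec$data)[2]
  if (nrow(X) != n) {
    abort(sprintf("Design matrix has %d rows but recording has %d samples.",
                  nrow(X), n))
  }
  p <- ncol(X)
  n_ch <- dim(rec$data)[1]
  betas <- matrix(NA_real_, n_ch, p, dimnames = list(NULL, colnames(X)))
  sigma2 <- rep(NA_real_, n_ch)
  phi <- rep(NA_real_, n_ch)
  xtx_inv <- array(NA_real_, c(p, p, n_ch))
  dof <- n - p
  for (ch in seq_len(n_ch)) {
    if (!rec$usable[ch]) next
    y <- rec$data[ch, , plane]
    w <- prewhiten_ar1(y, X)
    fit <- qr(w$X)
    b <- qr.coef(fit, w$y)
    r <- w$y - w$X %*% b
    betas[ch, ] <- b
    sigma2[ch] <- sum(r^2) / dof
    phi[ch] <- w$phi
    xtx_inv[, , ch] <- chol2inv(qr.R(fit))
  }
  structure(list(betas = betas, sigma2 = sigma2, phi = phi, dof = dof,
                 xtx_inv = xtx_inv,
                 task_regressors = attr(X, "task_regressors"),
                 chromophore = chromophore, usable = rec$usable),
            class = "nirs_first_level")
}

#' @export
print.nirs_first_level <- function(x, ...) {
  cat(sprintf("<nirs_first_level> %d channels (%d usable), %s, dof = %d\n",
              nrow(x$betas), sum(x$usable), x$chromophore, x$dof))
  invisible(x)
}

#' Linear contrast of first-level coefficients
#'
#' Computes `c'beta` per channel with variance `c'(X'X)^-1 c * sigma^2` on
#' the whitened model. Weights address the task regressors in order; the
#' constant column gets weight 0.
#'
#' @param res An `nirs_first_level`.
#' @param weights Numeric weights, one per task regressor (or a named vector
#'   over a subset of them).
#' @return Tibble with `channel`, `estimate`, `variance`, `se`, `t`.
#' @export
compute_contrast <- function(res, weights) {
  stopifnot(inherits(res, "nirs_first_level"))
  k <- length(res$task_regressors)
  if (!is.null(names(weights))) {
    bad <- setdiff(names(weights), res$task_regressors)
    if (length(bad)) {
      abort(sprintf("Unknown regressor(s) in weights: %s",
                    paste(bad, collapse = ", ")))
    }
    w <- stats::setNames(numeric(k), res$task_regressors)
    w[names(weights)] <- weights
    weights <- w
  }
  if (length(weights) != k) {
    abort(sprintf("`weights` must have one entry per task regressor (%d).", k))
  }
  if (all(weights == 0)) abort("`weights` must not be all zero.")
  cvec <- c(weights, 0)   # constant column
  est <- drop(res$betas %*% cvec)
  n_ch <- nrow(res$betas)
  var_c <- vapply(seq_len(n_ch), function(ch) {
    if (is.na(res$sigma2[ch])) return(NA_real_)
    drop(t(cvec) %*% res$xtx_inv[, , ch] %*% cvec) * res$sigma2[ch]
  }, numeric(1))
  tibble(channel = seq_len(n_ch), estimate = est, variance = var_c,
         se = sqrt(var_c), t = est / sqrt(var_c))
}
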