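#' Preprocessing configuration
#'
#' Parameters of the denoising chain applied to hemoglobin recordings:
#' moving-window spline motion correction (1 s window, threshold factor 3,
#' smoothing factor 5), zero-phase Butterworth band-stop filters over the
#' respiratory/Mayer (0.12-0.35 Hz) and cardiac (0.7-2.0 Hz) bands, and a
#' discrete-cosine-transform high-pass removing drift below 0.01 Hz.
#'
#' @param window_s Moving-window length for artifact detection (s).
#' @param threshold_factor Multiple of the channel's median moving-window SD
#'   above which samples are flagged as motion.
#' @param smoothing_factor Spline smoothing control of the correction; mapped
#'   to `smooth.spline`'s `spar` as `min(1, smoothing_factor / 10)`.
#' @param bandstop List of `(lower, upper)` Hz pairs to suppress.
#' @param highpass_cutoff Drift cutoff (Hz) of the DCT high-pass.
#' @param filter_order Butterworth order of each band-stop (default 4).
#' @param age_years Participant age used for the differential pathlength
#'   factor.
#' @return An object of class `nirs_preprocess_config`.
#' @export
preprocess_config <- function(window_s = 1.0,
                              threshold_factor = 3.0,
                              smoothing_factor = 5.0,
                              bandstop = list(c(0.12, 0.35), c(0.7, 2.0)),
                              highpass_cutoff = 0.01,
                              filter_order = 4L,
                              age_years = 5.2) {
  assert_scalar_number(window_s, "window_s", positive = TRUE)
  assert_scalar_number(threshold_factor, "threshold_factor", positive = TRUE)
  assert_scalar_number(smoothing_factor, "smoothing_factor", positive = TRUE)
  assert_scalar_number(highpass_cutoff, "highpass_cutoff", positive = TRUE)
  for (b in bandstop) {
    if (length(b) != 2 || b[1] <= 0 || b[1] >= b[2]) {
      abort("Each band-stop must be c(lower, upper) with 0 < lower < upper.")
    }
  }
  structure(list(window_s = window_s, threshold_factor = threshold_factor,
                 smoothing_factor = smoothing_factor, bandstop = bandstop,
                 highpass_cutoff = highpass_cutoff,
                 filter_order = as.integer(filter_order),
                 age_years = age_years),
            class = "nirs_preprocess_config")
}

check_bands <- function(cfg, fs) {
  nyq <- fs / 2
  for (b in cfg$bandstop) {
    if (b[2] >= nyq) {
      abort(sprintf(
        "Band-stop upper edge %.3g Hz is not below the Nyquist frequency %.3g Hz at fs = %g Hz.",
        b[2], nyq, fs))
    }
  }
  invisible(cfg)
}

# Centered moving-window standard deviation (window in samples).
moving_sd <- function(x, w) {
  k <- rep(1 / w, w)
  m1 <- stats::filter(x, k, sides = 2)
  m2 <- stats::filter(x^2, k, sides = 2)
  v <- pmax(m2 - m1^2, 0)
  out <- sqrt(as.numeric(v))
  # pad the half-windows at both ends with the nearest defined value
  idx <- which(!is.na(out))
  out[seq_len(idx[1] - 1L)] <- out[idx[1]]
  out[seq((idx[length(idx)] + 1L), length.out = length(out) - idx[length(idx)])] <-
    out[idx[length(idx)]]
  out
}

flag_to_segments <- function(flag, pad) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) return(matrix(integer(0), ncol = 2))
  seg <- cbind(pmax(1L, starts[keep] - pad),
               pmin(length(flag), ends[keep] + pad))
  # merge overlapping segments and fragments of one artifact (gap < pad):
  # detection fires on an artifact's steep flanks, so nearby fragments
  # belong together.
  merged <- list(seg[1, ])
  for (i in seq_len(nrow(seg))[-1]) {
    last <- merged[[length(merged)]]
    if (seg[i, 1] <= last[2] + pad) {
      merged[[length(merged)]] <- c(last[1], max(last[2], seg[i, 2]))
    } else {
      merged[[length(merged) + 1L]] <- seg[i, ]
    }
  }
  do.call(rbind, merged)
}

correct_channel_motion <- function(y, fs, cfg) {
  n <- length(y)
  w <- max(2L, round(cfg$window_s * fs))
  mwsd <- moving_sd(y, w)
  ref <- median(mwsd)
  flag <- mwsd > cfg$threshold_factor * ref
  if (ref == 0 || !any(flag)) {
    return(list(y = y, flag = rep(FALSE, n), segments = NULL, usable = TRUE))
  }
  segs <- flag_to_segments(flag, pad = 2L * w)
  # a channel whose merged artifact segments span (nearly) all of it has no
  # clean baseline left to correct against
  if (sum(segs[, 2] - segs[, 1] + 1L) > 0.9 * n) {
    return(list(y = y, flag = flag, segments = NULL, usable = FALSE))
  }
  spar <- min(1, cfg$smoothing_factor / 10)
  for (i in seq_len(nrow(segs))) {
    a <- segs[i, 1]; b <- segs[i, 2]
    idx <- a:b
    # local linear baseline fitted just before the artifact and extrapolated
    # across it; falls back to the post-segment side at the recording start
    pre_src <- if (a > 5L) max(1L, a - 4L * w):(a - 1L) else integer(0)
    post_src <- if (b + w <= n) (b + w):min(n, b + 4L * w) else integer(0)
    src <- if (length(pre_src) >= 5L) pre_src else post_src
    baseline <- if (length(src) >= 5L) {
      cf <- stats::coef(stats::lm.fit(cbind(1, src), y[src]))
      function(j) cf[1] + cf[2] * j
    } else {
      mu <- mean(y[if (length(src)) src else idx])
      function(j) rep(mu, length(j))
    }
    seg <- y[idx]
    trend <- if (length(idx) >= 8L) {
      fitted(smooth.spline(idx, seg, spar = spar))
    } else {
      rep(mean(seg), length(idx))
    }
    y[idx] <- seg - trend + baseline(idx)
    # Remove a persisting baseline shift. The step is estimated over long
    # balanced windows (up to 8 s each side, skipping 1 window next to the
    # segment) so slow physiological oscillation averages out, and applied
    # only when clearly larger than the windows' own variability.
    pre_long <- if (a > w + 5L) max(1L, a - 8L * w):(a - w) else integer(0)
    post_long <- if (b + w <= n) (b + w):min(n, b + 8L * w) else integer(0)
    if (length(pre_long) >= 10L && length(post_long) >= 10L && b < n) {
      delta <- mean(y[post_long]) - mean(y[pre_long])
      se <- sqrt(stats::var(y[pre_long]) / length(pre_long) +
                   stats::var(y[post_long]) / length(post_long))
      if (abs(delta) > 3 * se) {
        y[(b + 1L):n] <- y[(b + 1L):n] - delta
      }
    }
  }
  list(y = y, flag = flag, segments = segs, usable = TRUE)
}

#' Detect and correct motion artifacts
#'
#' Per channel, samples whose 1 s moving-window standard deviation exceeds
#' `threshold_factor` times the channel's median window deviation are flagged
#' as motion. Each flagged segment is corrected by subtracting a
#' smoothing-spline fit of the segment (the artifact trend) and re-anchoring
#' it to the neighbouring baseline; any residual step between the pre- and
#' post-segment baselines is removed by re-levelling the subsequent samples.
#' A channel flagged in its entirety is left untouched and marked unusable.
#'
#' @param rec A `nirs_recording` (hemoglobin planes by default convention).
#' @param cfg A [preprocess_config()].
#' @return A list with `recording` (corrected) and `mask` (an
#'   `nirs_artifact_mask`: per-channel logical matrix plus a segment table).
#' @export
correct_motion <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "nirs_recording"))
  n <- dim(rec$data)[2]
  if (n <= round(cfg$window_s * rec$fs)) {
    abort("Recording is not longer than the detection window.")
  }
  n_ch <- dim(rec$data)[1]
  flag <- matrix(FALSE, n_ch, n)
  seg_rows <- list()
  usable <- rec$usable
  out <- rec$data
  for (ch in seq_len(n_ch)) {
    for (p in seq_along(rec$planes)) {
      res <- correct_channel_motion(rec$data[ch, , p], rec$fs, cfg)
      out[ch, , p] <- res$y
      flag[ch, ] <- flag[ch, ] | res$flag
      if (!res$usable) {
        usable[ch] <- FALSE
        warn(sprintf("Channel %d is motion-flagged in its entirety; marked unusable.", ch))
      }
      if (!is.null(res$segments)) {
        seg_rows[[length(seg_rows) + 1L]] <-
          tibble(channel = ch, plane = rec$planes[p],
                 start = res$segments[, 1], end = res$segments[, 2])
      }
    }
  }
  rec$data <- out
  rec$usable <- usable
  rec$stage <- "motion_corrected"
  rec$stages <- c(rec$stages, "correct_motion")
  mask <- structure(
    list(flag = flag,
         segments = if (length(seg_rows)) dplyr::bind_rows(seg_rows) else
           tibble(channel = integer(), plane = character(),
                  start = integer(), end = integer())),
    class = "nirs_artifact_mask")
  list(recording = rec, mask = mask)
}

# Zero-phase IIR filtering with odd-reflection padding and steady-state
# initial conditions at the edge level; signal::filtfilt alone starts from
# zero state, which leaves long edge transients for narrow low-frequency
# band-stops.
filtfilt_padded <- function(b, a, x) {
  nf <- max(length(a), length(b))
  b <- c(b, numeric(nf - length(b)))
  a <- c(a, numeric(nf - length(a)))
  npad <- max(3L * (nf - 1L), 100L)
  n <- length(x)
  pre <- 2 * x[1] - x[(npad + 1):2]
  post <- 2 * x[n] - x[(n - 1):(n - npad)]
  xx <- c(pre, x, post)
  g <- sum(b) / sum(a)
  one_pass <- function(z) {
    as.numeric(signal::filter(b, a, z, init.x = rep(z[1], nf - 1),
                              init = rep(z[1] * g, nf - 1)))
  }
  y <- one_pass(xx)
  y <- rev(one_pass(rev(y)))
  y[(npad + 1):(npad + n)]
}

# DCT-II basis columns with frequency below `cutoff` (SPM drift convention),
# including the constant term.
dct_drift_basis <- function(n, fs, cutoff) {
  kmax <- floor(2 * n * cutoff / fs)
  k <- 0:kmax
  tt <- 2 * (0:(n - 1)) + 1
  B <- cos(outer(tt, k) * pi / (2 * n))
  # orthonormalise
  B[, 1] <- B[, 1] / sqrt(n)
  if (length(k) > 1) B[, -1] <- B[, -1] / sqrt(n / 2)
  B
}

#' Zero-phase band-stop and DCT high-pass temporal filtering
#'
#' Applies forward-backward (zero-phase) Butterworth band-stop filters over
#' each configured physiological band, then removes slow drift by projecting
#' out a discrete-cosine-transform basis restricted to frequencies below
#' `highpass_cutoff` (constant term included).
#'
#' @inheritParams correct_motion
#' @return The filtered `nirs_recording` (same length).
#' @export
temporal_filter <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "nirs_recording"))
  check_bands(cfg, rec$fs)
  n <- dim(rec$data)[2]
  filters <- lapply(cfg$bandstop, function(b) {
    signal::butter(cfg$filter_order, b / (rec$fs / 2), type = "stop")
  })
  B <- dct_drift_basis(n, rec$fs, cfg$highpass_cutoff)
  out <- rec$data
  n_ch <- dim(rec$data)[1]
  for (p in seq_along(rec$planes)) {
    y <- t(matrix(rec$data[, , p], nrow = n_ch))   # samples x channels
    for (f in filters) {
      y <- apply(y, 2, function(col) filtfilt_padded(f$b, f$a, col))
    }
    y <- y - B %*% crossprod(B, y)
    out[, , p] <- t(y)
  }
  rec$data <- out
  rec$stage <- "filtered"
  rec$stages <- c(rec$stages, "temporal_filter")
  rec
}

#' AR(1) pre-whitening of a channel time series and design matrix
#'
#' Estimates the lag-1 autoregressive coefficient from the ordinary
#' least-squares residuals of `y` on `X`, then applies the AR(1) whitening
#' transform `y_t - phi * y_{t-1}` (first sample scaled by `sqrt(1 - phi^2)`)
#' to both `y` and `X`.
#'
#' @param y Numeric response vector.
#' @param X Design matrix with `length(y)` rows.
#' @return List with whitened `y`, `X`, and the `phi` estimate in (-1, 1).
#' @export
prewhiten_ar1 <- function(y, X) {
  X <- as.matrix(X)
  n <- length(y)
  if (nrow(X) != n) abort("`X` must have length(y) rows.")
  beta <- qr.coef(qr(X), y)
  r <- y - X %*% beta
  denom <- sum(r^2)
  phi <- if (denom < 1e-300) 0 else sum(r[-1] * r[-n]) / denom
  if (abs(phi) >= 1) {
    warn(sprintf("AR(1) estimate %.3f clipped to +/-0.99.", phi))
    phi <- sign(phi) * 0.99
  }
  w_y <- c(sqrt(1 - phi^2) * y[1], y[-1] - phi * y[-n])
  w_X <- rbind(sqrt(1 - phi^2) * X[1, , drop = FALSE],
               X[-1, , drop = FALSE] - phi * X[-n, , drop = FALSE])
  list(y = w_y, X = w_X, phi = phi)
}
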