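fs <- 10

test_that("a clean oscillation is left untouched by motion correction", {
  t <- (0:2999) / fs
  rec <- matrix_recording(matrix(sin(2 * pi * 0.05 * t), 1, byrow = TRUE))
  res <- correct_motion(rec)
  expect_false(any(res$mask$flag))
  expect_equal(res$recording$data, rec$data)
  expect_true(res$recording$usable)
})

test_that("an injected 10-sd spike is detected and corrected", {
  set.seed(21)
  n <- 3000
  clean <- 0.08 * sin(2 * pi * 0.1 * (0:(n - 1)) / fs) + rnorm(n, 0, 0.05)
  centre <- 1500; sdw <- 0.5 * fs / 4
  y <- clean + 0.5 * exp(-((1:n) - centre)^2 / (2 * sdw^2))
  res <- correct_motion(matrix_recording(matrix(y, 1)))
  span <- floor(centre - 2 * sdw):ceiling(centre + 2 * sdw)
  det <- rep(FALSE, n)
  s <- res$mask$segments
  for (i in seq_len(nrow(s))) det[s$start[i]:s$end[i]] <- TRUE
  expect_gte(mean(det[span]), 0.9)
  z <- res$recording$data[1, , 1]
  expect_lt(sd(z[span] - clean[span]) / 0.05, 3)
})

test_that("a baseline shift is re-levelled by at least 80 percent", {
  set.seed(22)
  n <- 3000
  clean <- 0.08 * sin(2 * pi * 0.1 * (0:(n - 1)) / fs) + rnorm(n, 0, 0.05)
  y <- clean; y[1501:n] <- y[1501:n] + 0.8
  res <- correct_motion(matrix_recording(matrix(y, 1)))
  z <- res$recording$data[1, , 1]
  step_after <- mean(z[1600:1750]) - mean(z[1300:1450])
  expect_lt(abs(step_after) / 0.8, 0.2)
})

test_that("an entirely artifactual channel is marked unusable, not an error", {
  set.seed(23)
  n <- 1200
  # spikes every 5 s: the padded, merged artifact segments blanket the channel
  y <- rnorm(n, 0, 0.01)
  centres <- seq(20, n, by = 50)
  for (cc in centres) y <- y + 5 * exp(-((1:n) - cc)^2 / (2 * 2^2))
  rec <- matrix_recording(matrix(y, 1))
  expect_warning(res <- correct_motion(rec), "unusable")
  expect_false(res$recording$usable[1])
})

test_that("band-stop and DCT filters hit their response targets", {
  n <- 4000
  t <- (0:(n - 1)) / fs
  retention <- function(freq) {
    rec <- matrix_recording(matrix(sin(2 * pi * freq * t), 1))
    out <- temporal_filter(rec)$data[1, , 1]
    sqrt(mean(out^2)) / sqrt(0.5)
  }
  expect_lte(retention(1.1), 0.10)      # cardiac band suppressed
  expect_lte(retention(0.25), 0.10)     # respiratory band suppressed
  expect_gte(retention(0.05), 0.90)     # task band preserved
  # DC and slow drift are removed by the DCT basis
  const <- matrix_recording(matrix(1, 1, n))
  expect_lt(max(abs(temporal_filter(const)$data)), 1e-5)
})

test_that("filtering is zero-phase and deterministic", {
  n <- 2000
  imp <- matrix(0, 1, n); imp[1, 1000] <- 1
  out <- temporal_filter(matrix_recording(imp))$data[1, , 1]
  # impulse response symmetric about the impulse -> no phase shift
  k <- 40
  expect_lt(max(abs(out[1000 + 1:k] - out[1000 - 1:k])), 1e-6)
  r1 <- temporal_filter(matrix_recording(imp))$data
  expect_identical(r1, temporal_filter(matrix_recording(imp))$data)
})

test_that("bands at or above Nyquist are rejected", {
  cfg <- preprocess_config(bandstop = list(c(0.7, 6.0)))
  rec <- matrix_recording(matrix(rnorm(1000), 1))
  expect_error(temporal_filter(rec, cfg), "Nyquist")
  expect_error(preprocess_config(bandstop = list(c(0.5, 0.2))), "lower")
})

test_that("AR(1) pre-whitening recovers phi and whitens residuals", {
  n <- 4000
  X <- cbind(1, rnorm(n))
  set.seed(31)
  reps <- t(replicate(5, {
    y <- as.numeric(arima.sim(list(ar = 0.5), n))
    w <- prewhiten_ar1(y, X)
    r <- w$y - w$X %*% qr.coef(qr(w$X), w$y)
    c(phi = w$phi, lag1 = cor(r[-1], r[-n]))
  }))
  expect_true(all(abs(reps[, "phi"] - 0.5) < 0.05))
  expect_true(all(abs(reps[, "lag1"]) < 0.1))
  # white noise -> phi near zero
  set.seed(32)
  w0 <- prewhiten_ar1(rnorm(n), X)
  expect_lt(abs(w0$phi), 0.1)
  # phi = 0 means the transform is the identity (constant response)
  yc <- rep(2, 100)
  wc <- prewhiten_ar1(yc, matrix(1, 100))
  expect_equal(wc$phi, 0)
  expect_equal(wc$y, yc)
})
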