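#' Canonical double-gamma hemodynamic response function
#'
#' Samples the canonical HRF — a positive gamma density peaking at `peak_s`
#' minus a scaled gamma density peaking at `undershoot_s` — on the acquisition
#' grid, normalised to unit peak. Gamma shapes are parameterised by their mode
#' (rate 1 per second), so the response peaks at exactly `peak_s` seconds.
#'
#' @param fs Sampling rate (Hz).
#' @param peak_s Time-to-peak of the positive lobe (s, default 6).
#' @param undershoot_s Time-to-trough of the undershoot lobe (s, default 16).
#' @param ratio Peak-to-undershoot amplitude ratio (default 6).
#' @param duration_s Kernel support (s, default 32); the returned kernel has
#'   `round(duration_s * fs) + 1` samples.
#' @return Numeric kernel with maximum exactly 1.
#' @export
canonical_hrf <- function(fs, peak_s = 6, undershoot_s = 16, ratio = 6,
                          duration_s = 32) {
  assert_scalar_number(fs, "fs", positive = TRUE)
  assert_scalar_number(peak_s, "peak_s", positive = TRUE)
  assert_scalar_number(undershoot_s, "undershoot_s", positive = TRUE)
  assert_scalar_number(ratio, "ratio", positive = TRUE)
  if (peak_s >= undershoot_s) abort("`peak_s` must be < `undershoot_s`.")
  shape1 <- peak_s + 1          # mode of gamma(shape, rate = 1) is shape - 1
  shape2 <- undershoot_s + 1
  raw <- function(t) {
    stats::dgamma(t, shape = shape1, rate = 1) -
      stats::dgamma(t, shape = shape2, rate = 1) / ratio
  }
  t <- seq(0, duration_s, by = 1 / fs)
  h <- raw(t)
  h / max(h)
}
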