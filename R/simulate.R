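#' Ground-truth effect map for simulation
#'
#' Peak oxy-hemoglobin response amplitude (uM) of every channel under every
#' task condition, plus the HbR/HbO coupling ratio and an optional
#' per-condition hemodynamic lag.
#'
#' @param amplitude Numeric matrix, channels x conditions, with condition
#'   labels as column names (baseline carries no column). Units uM.
#' @param hbr_ratio HbR amplitude as a (negative) fraction of the HbO task
#'   component; default -0.3, the typical antagonistic response.
#' @param condition_lag_s Named numeric vector of extra response latency (s)
#'   per condition; unnamed conditions get 0.
#' @return An object of class `nirs_effect_map`.
#' @export
effect_map <- function(amplitude, hbr_ratio = -0.3, condition_lag_s = NULL) {
  if (!is.matrix(amplitude) || is.null(colnames(amplitude))) {
    abort("`amplitude` must be a matrix with condition column names.")
  }
  if (!all(is.finite(amplitude))) abort("`amplitude` must be finite.")
  assert_scalar_number(hbr_ratio, "hbr_ratio")
  lag <- stats::setNames(numeric(ncol(amplitude)), colnames(amplitude))
  if (!is.null(condition_lag_s)) {
    lag[names(condition_lag_s)] <- condition_lag_s
  }
  structure(list(amplitude = amplitude, hbr_ratio = hbr_ratio,
                 condition_lag_s = lag),
            class = "nirs_effect_map")
}

#' Build an effect map from ROI-level amplitudes
#'
#' @param montage A `nirs_montage`.
#' @param effects Data frame with columns `condition`, `roi` (ROI name,
#'   optionally `"DLPFC-left"` style) and `amplitude` (uM); every channel of
#'   the ROI receives the amplitude (summed over rows hitting the channel).
#' @param conditions Condition labels defining the columns; defaults to those
#'   appearing in `effects`.
#' @inheritParams effect_map
#' @return An `nirs_effect_map`.
#' @export
roi_effect_map <- function(montage, effects, conditions = NULL,
                           hbr_ratio = -0.3, condition_lag_s = NULL) {
  stopifnot(inherits(montage, "nirs_montage"), is.data.frame(effects))
  conditions <- conditions %||% unique(effects$condition)
  amp <- matrix(0, nrow(montage$channels), length(conditions),
                dimnames = list(NULL, conditions))
  for (i in seq_len(nrow(effects))) {
    ch <- roi_channels(montage, effects$roi[i])
    amp[ch, effects$condition[i]] <- amp[ch, effects$condition[i]] +
      effects$amplitude[i]
  }
  effect_map(amp, hbr_ratio = hbr_ratio, condition_lag_s = condition_lag_s)
}

#' Physiological and instrumental noise specification
#'
#' Defaults are plausible for continuous-wave fNIRS concentration signals on
#' the uM scale: cardiac pulsation near 1.1 Hz, respiration near 0.25 Hz,
#' Mayer waves near 0.1 Hz, slow linear drift, and AR(1)-correlated plus
#' white measurement noise, with occasional motion spikes and baseline
#' shifts.
#'
#' @param cardiac_freq,cardiac_amp Cardiac frequency (Hz) and amplitude (uM).
#' @param resp_freq,resp_amp Respiratory frequency/amplitude.
#' @param mayer_freq,mayer_amp Mayer-wave frequency/amplitude.
#' @param drift_sd Standard deviation of the random per-channel linear drift
#'   slope (uM per minute).
#' @param ar1_phi Lag-1 coefficient of the AR(1) noise component, in [0, 1).
#' @param ar1_sd Innovation standard deviation of the AR(1) component (uM).
#' @param white_sd White measurement-noise standard deviation (uM).
#' @param spike_rate_per_min,spike_amp Motion-spike Poisson rate (events/min)
#'   and amplitude (uM); spikes are Gaussian-shaped transients of 0.2-0.8 s.
#' @param shift_rate_per_min,shift_amp Baseline-shift rate and step size (uM).
#' @param systemic If `TRUE`, the physiological oscillations are systemic:
#'   one phase per oscillation shared by every channel (with channel-specific
#'   amplitude jitter), as blood-pressure waves are; if `FALSE` (default)
#'   phases are drawn per channel.
#' @return An object of class `nirs_noise_spec`.
#' @export
noise_spec <- function(cardiac_freq = 1.1, cardiac_amp = 0.15,
                       resp_freq = 0.25, resp_amp = 0.10,
                       mayer_freq = 0.10, mayer_amp = 0.08,
                       drift_sd = 0.05,
                       ar1_phi = 0.3, ar1_sd = 0.05, white_sd = 0.05,
                       spike_rate_per_min = 0, spike_amp = 1.0,
                       shift_rate_per_min = 0, shift_amp = 0.8,
                       systemic = FALSE) {
  if (ar1_phi < 0 || ar1_phi >= 1) abort("`ar1_phi` must lie in [0, 1).")
  if (min(cardiac_amp, resp_amp, mayer_amp, drift_sd, ar1_sd, white_sd,
          spike_rate_per_min, shift_rate_per_min) < 0) {
    abort("Noise amplitudes and rates must be non-negative.")
  }
  structure(list(cardiac_freq = cardiac_freq, cardiac_amp = cardiac_amp,
                 resp_freq = resp_freq, resp_amp = resp_amp,
                 mayer_freq = mayer_freq, mayer_amp = mayer_amp,
                 drift_sd = drift_sd, ar1_phi = ar1_phi, ar1_sd = ar1_sd,
                 white_sd = white_sd,
                 spike_rate_per_min = spike_rate_per_min,
                 spike_amp = spike_amp,
                 shift_rate_per_min = shift_rate_per_min,
                 shift_amp = shift_amp,
                 systemic = isTRUE(systemic)),
            class = "nirs_noise_spec")
}

#' A noise specification with every component silenced
#' @return An `nirs_noise_spec` whose simulation contribution is identically 0.
#' @export
noise_spec_silent <- function() {
  noise_spec(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0, drift_sd = 0,
             ar1_phi = 0, ar1_sd = 0, white_sd = 0,
             spike_rate_per_min = 0, shift_rate_per_min = 0)
}

new_recording <- function(data, planes, fs, stage, design = NULL,
                          montage = NULL, usable = NULL, stages = stage) {
  structure(list(data = data, planes = planes, fs = fs, stage = stage,
                 design = design, montage = montage,
                 usable = usable %||% rep(TRUE, dim(data)[1]),
                 stages = stages),
            class = "nirs_recording")
}

#' @export
print.nirs_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<nirs_recording> %d channels x %d samples x (%s) at %g Hz, stage '%s'\n",
              d[1], d[2], paste(x$planes, collapse = ", "), x$fs, x$stage))
  cat("stages:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

# Unit-peak condition regressor: boxcar convolved with the HRF, scaled so a
# unit effect amplitude means a 1 uM peak response. Shared by the simulator
# and the GLM design matrix so recovered coefficients are in amplitude units.
condition_regressor <- function(design, condition, hrf, n) {
  reg <- convolve_truncate(condition_boxcar(design, condition), hrf)
  reg[seq_len(n)] / max(reg)
}

# channels x samples noise-free task component for one chromophore plane.
task_component <- function(design, effects, hrf, n) {
  conds <- colnames(effects$amplitude)
  fs <- design$fs
  comp <- matrix(0, nrow(effects$amplitude), n)
  for (cond in conds) {
    if (all(effects$amplitude[, cond] == 0)) next
    reg <- condition_regressor(design, cond, hrf, n)
    lag <- round(effects$condition_lag_s[[cond]] * fs)
    if (lag > 0) {
      reg <- c(numeric(lag), reg)[seq_len(n)]
    } else if (lag < 0) {
      reg <- c(reg[-seq_len(-lag)], numeric(-lag))
    }
    comp <- comp + effects$amplitude[, cond, drop = FALSE] %*%
      matrix(reg, nrow = 1)
  }
  comp
}

# One plane of structured + stochastic noise (channels x samples).
noise_component <- function(noise, n_ch, n, fs) {
  out <- matrix(0, n_ch, n)
  t <- (seq_len(n) - 1) / fs
  add_sine <- function(out, freq, amp) {
    if (amp == 0) return(out)
    if (freq >= fs / 2) abort(sprintf(
      "Oscillation at %.3g Hz is not below the Nyquist frequency %.3g Hz.",
      freq, fs / 2))
    if (noise$systemic) {
      phase <- rep(runif(1, 0, 2 * pi), n_ch)
      amp <- amp * runif(n_ch, 0.5, 1.5)     # channel-specific coupling gain
    } else {
      phase <- runif(n_ch, 0, 2 * pi)
    }
    out + amp * sin(matrix(2 * pi * freq * t, n_ch, n, byrow = TRUE) + phase)
  }
  out <- add_sine(out, noise$cardiac_freq, noise$cardiac_amp)
  out <- add_sine(out, noise$resp_freq, noise$resp_amp)
  out <- add_sine(out, noise$mayer_freq, noise$mayer_amp)
  if (noise$drift_sd > 0) {
    slope <- rnorm(n_ch, 0, noise$drift_sd)          # uM per minute
    out <- out + outer(slope, t / 60)
  }
  if (noise$ar1_sd > 0) {
    innov <- matrix(rnorm(n_ch * n, 0, noise$ar1_sd), n_ch, n)
    ar <- t(apply(innov, 1, function(e) {
      as.numeric(stats::filter(e, noise$ar1_phi, method = "recursive"))
    }))
    out <- out + ar
  }
  if (noise$white_sd > 0) {
    out <- out + matrix(rnorm(n_ch * n, 0, noise$white_sd), n_ch, n)
  }
  out
}

# Motion artifacts shared across chromophore planes. Returns the artifact
# waveform (channels x samples) and the injected segments.
artifact_component <- function(noise, n_ch, n, fs) {
  out <- matrix(0, n_ch, n)
  segs <- list()
  minutes <- n / fs / 60
  t <- seq_len(n)
  for (ch in seq_len(n_ch)) {
    n_spike <- rpois(1, noise$spike_rate_per_min * minutes)
    for (i in seq_len(n_spike)) {
      centre <- runif(1, 1, n)
      width_s <- runif(1, 0.2, 0.8)
      sdw <- width_s * fs / 4
      amp <- sample(c(-1, 1), 1) * noise$spike_amp
      out[ch, ] <- out[ch, ] + amp * exp(-(t - centre)^2 / (2 * sdw^2))
      segs[[length(segs) + 1L]] <- tibble(
        channel = ch, type = "spike",
        start = max(1L, floor(centre - 2 * sdw)),
        end = min(n, ceiling(centre + 2 * sdw)))
    }
    n_shift <- rpois(1, noise$shift_rate_per_min * minutes)
    for (i in seq_len(n_shift)) {
      at <- sample.int(n - 1L, 1)
      amp <- sample(c(-1, 1), 1) * noise$shift_amp
      out[ch, (at + 1L):n] <- out[ch, (at + 1L):n] + amp
      segs[[length(segs) + 1L]] <- tibble(channel = ch, type = "shift",
                                          start = at, end = min(n, at + 1L))
    }
  }
  list(waveform = out,
       segments = if (length(segs)) dplyr::bind_rows(segs) else
         tibble(channel = integer(), type = character(),
                start = integer(), end = integer()))
}

#' Simulate one subject's hemoglobin recording with ground truth
#'
#' Implements the generative model the downstream GLM assumes: per channel,
#' HbO = sum over conditions of amplitude x (boxcar convolved with the
#' canonical HRF), plus physiological sinusoids with randomised phases,
#' linear drift, AR(1)-plus-white noise, and motion artifacts (Gaussian
#' spikes and Heaviside baseline shifts, common to both chromophores). HbR is
#' `hbr_ratio` times the HbO task component plus its own independent noise.
#'
#' @param design A `nirs_block_design`.
#' @param montage A `nirs_montage`; its channel count must match `effects`.
#' @param effects An `nirs_effect_map`.
#' @param noise An `nirs_noise_spec`.
#' @param seed Integer seed; identical seeds give bit-identical recordings.
#' @param hrf HRF kernel; default [canonical_hrf()] at the design's rate.
#' @return A list with elements `recording` (a `nirs_recording`, planes
#'   HbO/HbR in uM) and `truth` (noise-free task component, true amplitudes,
#'   lags, and injected artifact segments).
#' @export
simulate_subject <- function(design, montage, effects,
                             noise = noise_spec(), seed = 1L,
                             hrf = canonical_hrf(design$fs)) {
  stopifnot(inherits(design, "nirs_block_design"),
            inherits(montage, "nirs_montage"),
            inherits(effects, "nirs_effect_map"),
            inherits(noise, "nirs_noise_spec"))
  n_ch <- nrow(montage$channels)
  if (nrow(effects$amplitude) != n_ch) {
    abort(sprintf("Effect amplitude matrix has %d rows but montage has %d channels.",
                  nrow(effects$amplitude), n_ch))
  }
  bad <- setdiff(colnames(effects$amplitude), task_conditions(design))
  if (length(bad)) {
    abort(sprintf("Effect map conditions not in design: %s",
                  paste(bad, collapse = ", ")))
  }
  fs <- design$fs
  n <- round(design$total_duration * fs)

  task_hbo <- task_component(design, effects, hrf, n)
  task_hbr <- effects$hbr_ratio * task_hbo

  sim <- with_seed(seed, {
    art <- artifact_component(noise, n_ch, n, fs)
    hbo <- task_hbo + noise_component(noise, n_ch, n, fs) + art$waveform
    hbr <- task_hbr + noise_component(noise, n_ch, n, fs) + art$waveform
    list(hbo = hbo, hbr = hbr, art = art)
  })

  data <- array(0, c(n_ch, n, 2))
  data[, , 1] <- sim$hbo
  data[, , 2] <- sim$hbr
  rec <- new_recording(data, c("HbO", "HbR"), fs, "hb_simulated",
                       design = design, montage = montage)
  truth <- list(task_hbo = task_hbo, amplitude = effects$amplitude,
                hbr_ratio = effects$hbr_ratio,
                condition_lag_s = effects$condition_lag_s,
                artifacts = sim$art$segments, seed = seed)
  list(recording = rec, truth = truth)
}

#' Simulate a cohort with between-subject amplitude variability
#'
#' Subject-specific effect amplitudes are the base amplitudes plus
#' channel-by-condition Gaussian deviations with standard deviation
#' `between_subject_sd`; per-subject seeds derive deterministically from
#' `seed`.
#'
#' @param n_subjects Number of subjects (>= 2).
#' @param design,montage,noise Shared study conditions.
#' @param base_effects Cohort-mean `nirs_effect_map`.
#' @param between_subject_sd Between-subject amplitude SD (uM).
#' @param seed Master seed.
#' @return A list of per-subject `simulate_subject()` results, with subject
#'   ids in names.
#' @export
simulate_cohort <- function(n_subjects, design, montage, base_effects,
                            between_subject_sd = 0.2,
                            noise = noise_spec(), seed = 1L) {
  if (n_subjects < 2) abort("`n_subjects` must be >= 2.")
  if (between_subject_sd < 0) abort("`between_subject_sd` must be >= 0.")
  seeds <- derive_seeds(seed, 2L * n_subjects)
  out <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    amp_i <- with_seed(seeds[i], {
      base_effects$amplitude +
        matrix(rnorm(length(base_effects$amplitude), 0, between_subject_sd),
               nrow(base_effects$amplitude))
    })
    eff_i <- effect_map(amp_i, hbr_ratio = base_effects$hbr_ratio,
                        condition_lag_s = base_effects$condition_lag_s)
    out[[i]] <- simulate_subject(design, montage, eff_i, noise,
                                 seed = seeds[n_subjects + i])
  }
  names(out) <- sprintf("sub-%02d", seq_len(n_subjects))
  out
}
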