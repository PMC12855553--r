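make_amp <- function(values = 0) {
  matrix(values, 38, 6, dimnames = list(NULL, six_conditions))
}

full_design <- build_block_design(blocks_per_condition = 3L, seed = 11)
montage <- build_montage()

test_that("zero effects and silent noise give an identically zero recording", {
  sim <- simulate_subject(full_design, montage, effect_map(make_amp(0)),
                          noise_spec_silent(), seed = 1)
  expect_true(all(sim$recording$data == 0))
})

test_that("a single active channel reproduces boxcar x HRF exactly (superposition)", {
  amp <- make_amp(0); amp[5, "dynamic-anger"] <- 1
  sim <- simulate_subject(full_design, montage, effect_map(amp),
                          noise_spec_silent(), seed = 1)
  hrf <- canonical_hrf(10)
  n <- round(full_design$total_duration * 10)
  reg <- nirsdecode:::condition_regressor(full_design, "dynamic-anger", hrf, n)
  expect_equal(sim$recording$data[5, , 1], reg)
  expect_equal(sim$recording$data[5, , 2], -0.3 * reg)
  expect_true(all(sim$recording$data[-5, , ] == 0))
  # two-condition simulation is the sum of the single-condition ones
  amp2 <- make_amp(0); amp2[5, "static-happiness"] <- 0.7
  both <- amp + amp2
  s_both <- simulate_subject(full_design, montage, effect_map(both),
                             noise_spec_silent(), seed = 1)
  s_b <- simulate_subject(full_design, montage, effect_map(amp2),
                          noise_spec_silent(), seed = 1)
  expect_equal(s_both$recording$data,
               sim$recording$data + s_b$recording$data)
})

test_that("simulation is deterministic in the seed", {
  eff <- effect_map(make_amp(0.5))
  s1 <- simulate_subject(full_design, montage, eff, noise_spec(), seed = 7)
  s2 <- simulate_subject(full_design, montage, eff, noise_spec(), seed = 7)
  s3 <- simulate_subject(full_design, montage, eff, noise_spec(), seed = 8)
  expect_identical(s1$recording$data, s2$recording$data)
  expect_false(identical(s1$recording$data, s3$recording$data))
  expect_false(anyNA(s1$recording$data))
})

test_that("shape mismatches and invalid noise are rejected", {
  bad <- effect_map(matrix(0, 10, 6, dimnames = list(NULL, six_conditions)))
  expect_error(simulate_subject(full_design, montage, bad), "38")
  expect_error(noise_spec(ar1_phi = 1.2), "ar1_phi")
  expect_error(noise_spec(white_sd = -1), "non-negative")
  expect_error(simulate_cohort(1, full_design, montage,
                               effect_map(make_amp(0))), "n_subjects")
})

test_that("a noise-only channel's periodogram peaks at the cardiac frequency", {
  ns <- noise_spec(cardiac_amp = 0.3, resp_amp = 0, mayer_amp = 0,
                   drift_sd = 0, ar1_sd = 0, white_sd = 0.02)
  sim <- simulate_subject(full_design, montage, effect_map(make_amp(0)),
                          ns, seed = 3)
  y <- sim$recording$data[1, , 1]
  sp <- stats::spec.pgram(y, plot = FALSE, taper = 0)
  f_peak <- sp$freq[which.max(sp$spec)] * 10      # cycles/sample -> Hz
  expect_lt(abs(f_peak - 1.1), 0.05)
})

test_that("between-subject amplitude variability matches its target", {
  # 200 subjects on a minimal design keep this cheap; check the empirical
  # SD of the truth amplitudes against the requested value
  des <- tiny_design()
  base <- effect_map(matrix(1, 38, 1, dimnames = list(NULL, "dynamic-anger")))
  cohort <- simulate_cohort(200, des, montage, base,
                            between_subject_sd = 0.3,
                            noise = noise_spec_silent(), seed = 5)
  amps <- vapply(cohort, function(s) s$truth$amplitude[1, 1], numeric(1))
  expect_lt(abs(sd(amps) - 0.3) / 0.3, 0.2)
  expect_equal(length(cohort), 200L)
  # zero variability -> identical truths
  c0 <- simulate_cohort(3, des, montage, base, between_subject_sd = 0,
                        noise = noise_spec_silent(), seed = 5)
  expect_equal(c0[[1]]$truth$amplitude, c0[[3]]$truth$amplitude)
})
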