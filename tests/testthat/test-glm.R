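des6 <- build_block_design(blocks_per_condition = 3L, seed = 17)
mont <- build_montage()

test_that("the design matrix has one HRF regressor per task condition plus a constant", {
  X <- build_design_matrix(des6)
  expect_equal(ncol(X), 7L)             # 6 conditions + constant
  expect_equal(colnames(X)[7], "constant")
  expect_equal(nrow(X), round(des6$total_duration * des6$fs))
  # a single-condition design gives 2 columns
  X1 <- build_design_matrix(tiny_design())
  expect_equal(ncol(X1), 2L)
  # the regressor peaks about one HRF peak time after block onset
  on <- des6$blocks$onset[des6$blocks$condition == "dynamic-anger"][1]
  reg <- X[, "dynamic-anger"]
  first_block <- round(on * 10) + 1:300
  peak_t <- (first_block[which.max(reg[first_block])] - 1) / 10
  expect_lt(abs((peak_t - on) - (6 + 13.5 / 2)), 1.6)  # boxcar centre + HRF lag
  # baseline-only designs are rejected
  empty <- des6; empty$blocks <- des6$blocks[des6$blocks$condition == "baseline", ]
  expect_error(build_design_matrix(empty), "task")
})

test_that("noise-free simulation recovers every beta to 1e-6", {
  amp <- matrix(runif(38 * 6, 0.2, 1.5), 38, 6,
                dimnames = list(NULL, six_conditions))
  sim <- simulate_subject(des6, mont, effect_map(amp),
                          noise_spec_silent(), seed = 1)
  X <- build_design_matrix(des6)
  fit <- fit_first_level(sim$recording, X)
  expect_lt(max(abs(fit$betas[, six_conditions] - amp)), 1e-6)
  expect_true(all(fit$dof > 0))
  # doubling the data doubles the betas
  rec2 <- sim$recording; rec2$data <- 2 * rec2$data
  fit2 <- fit_first_level(rec2, X)
  expect_equal(fit2$betas[, six_conditions], 2 * fit$betas[, six_conditions],
               tolerance = 1e-8)
  # tidy/glance expose the fit
  td <- tidy(fit)
  expect_equal(nrow(td), 38 * 7)
  expect_equal(glance(fit)$n_usable, 38L)
})

test_that("unusable channels get missing coefficients", {
  amp <- matrix(0.5, 38, 6, dimnames = list(NULL, six_conditions))
  sim <- simulate_subject(des6, mont, effect_map(amp), noise_spec(), seed = 2)
  rec <- sim$recording
  rec$usable[4] <- FALSE
  fit <- fit_first_level(rec, build_design_matrix(des6))
  expect_true(all(is.na(fit$betas[4, ])))
  expect_false(anyNA(fit$betas[-4, ]))
})

test_that("pure-noise channels give betas indistinguishable from zero", {
  amp <- matrix(0, 38, 6, dimnames = list(NULL, six_conditions))
  ns <- noise_spec(cardiac_amp = 0, resp_amp = 0, mayer_amp = 0, drift_sd = 0,
                   ar1_phi = 0.3, ar1_sd = 0.1, white_sd = 0.1)
  X <- build_design_matrix(des6)
  hits <- 0L; total <- 0L
  for (s in 1:3) {
    sim <- simulate_subject(des6, mont, effect_map(amp), ns, seed = s)
    fit <- fit_first_level(sim$recording, X)
    td <- tidy(fit)
    td <- td[td$term != "constant", ]
    hits <- hits + sum(abs(td$estimate) < 3 * td$std.error)
    total <- total + nrow(td)
  }
  expect_gte(hits / total, 0.97)
})

test_that("contrasts recover amplitude differences and scale with noise", {
  amp <- matrix(0.5, 38, 6, dimnames = list(NULL, six_conditions))
  amp[, "dynamic-anger"] <- 2
  amp[, "dynamic-neutral"] <- 0.5
  sim <- simulate_subject(des6, mont, effect_map(amp),
                          noise_spec_silent(), seed = 1)
  fit <- fit_first_level(sim$recording, build_design_matrix(des6))
  ct <- compute_contrast(fit, c("dynamic-anger" = 1, "dynamic-neutral" = -1))
  expect_equal(ct$estimate, rep(1.5, 38), tolerance = 1e-6)
  # equal betas -> zero contrast
  ct0 <- compute_contrast(fit, c("static-anger" = 1, "static-happiness" = -1))
  expect_equal(ct0$estimate, rep(0, 38), tolerance = 1e-6)
  # contrast variance is proportional to residual variance
  fitA <- fit; fitA$sigma2 <- rep(1, 38)
  fitB <- fit; fitB$sigma2 <- rep(4, 38)
  w <- c("dynamic-anger" = 1, "dynamic-neutral" = -1)
  expect_equal(compute_contrast(fitB, w)$variance,
               4 * compute_contrast(fitA, w)$variance)
  expect_error(compute_contrast(fit, rep(0, 6)), "zero")
  expect_error(compute_contrast(fit, c(bogus = 1)), "bogus")
})
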