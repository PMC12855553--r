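cats6 <- rep(c("anger", "happiness", "neutral"), each = 2)
states6 <- rep(c("dynamic", "static"), 3)

test_that("identical cell values give F = 0 and corrected p = 1", {
  arr <- array(1, c(5, 4, 6))
  m <- suppressWarnings(
    permutation_group_test(arr, cats6, states6, n_perm = 100, seed = 1))
  expect_true(all(m$F == 0))
  expect_true(all(m$p_fwer == 1))
  expect_true(all(m$p_fwer >= m$p_unc))
})

test_that("observed F values match the classical repeated-measures ANOVA", {
  set.seed(9)
  S <- 10
  arr <- array(rnorm(S * 3 * 6), c(S, 3, 6))
  arr[, 2, cats6 == "anger"] <- arr[, 2, cats6 == "anger"] + 1
  m <- permutation_group_test(arr, cats6, states6, n_perm = 100, seed = 1)
  for (ch in 1:3) {
    df <- data.frame(y = as.vector(t(arr[, ch, ])),
                     subj = factor(rep(seq_len(S), each = 6)),
                     cat = factor(rep(cats6, S)),
                     st = factor(rep(states6, S)))
    fit <- summary(stats::aov(y ~ cat * st + Error(subj / (cat * st)),
                              data = df))
    f_ref <- vapply(fit[2:4], function(x) x[[1]][1, "F value"], numeric(1))
    f_mine <- m$F[m$channel == ch]
    expect_equal(unname(f_mine), unname(f_ref), tolerance = 1e-10)
  }
})

test_that("corrected p falls with effect size and localises true effects", {
  set.seed(12)
  base <- array(rnorm(12 * 6 * 6), c(12, 6, 6))
  p_at <- function(delta) {
    arr <- base
    arr[, 1, cats6 == "anger"] <- arr[, 1, cats6 == "anger"] + delta
    m <- permutation_group_test(arr, cats6, states6, n_perm = 300, seed = 4)
    m$p_fwer[m$channel == 1 & m$effect == "category"]
  }
  p_small <- p_at(0.5); p_big <- p_at(3)
  expect_lte(p_big, p_small)
  # a strong effect is declared on the carrying channel only
  arr <- base
  arr[, 1, cats6 == "anger"] <- arr[, 1, cats6 == "anger"] + 4
  m <- permutation_group_test(arr, cats6, states6, n_perm = 300, seed = 4)
  catmap <- m[m$effect == "category", ]
  expect_true(catmap$significant[catmap$channel == 1])
  expect_false(any(catmap$significant[catmap$channel != 1]))
})

test_that("permutation p-values are invariant to channel order and subjects are exchangeable", {
  set.seed(13)
  arr <- array(rnorm(8 * 5 * 6), c(8, 5, 6))
  m1 <- permutation_group_test(arr, cats6, states6, n_perm = 200, seed = 2)
  perm_ch <- c(3, 1, 5, 2, 4)
  m2 <- permutation_group_test(arr[, perm_ch, , drop = FALSE], cats6, states6,
                               n_perm = 200, seed = 2)
  expect_equal(m2$p_fwer[m2$channel == 1], m1$p_fwer[m1$channel == 3])
  perm_s <- sample(8)
  m3 <- permutation_group_test(arr[perm_s, , , drop = FALSE], cats6, states6,
                               n_perm = 200, seed = 2)
  expect_equal(m3$F, m1$F)
})

test_that("for a single channel the corrected p equals the uncorrected p", {
  set.seed(14)
  arr <- array(rnorm(10 * 1 * 6), c(10, 1, 6))
  m <- permutation_group_test(arr, cats6, states6, n_perm = 500, seed = 3)
  expect_equal(m$p_fwer, m$p_unc)
})

test_that("subjects with missing cells are dropped, few permutations warn", {
  arr <- array(rnorm(5 * 3 * 6), c(5, 3, 6))
  arr[2, 1, 3] <- NA
  expect_message(
    m <- permutation_group_test(arr, cats6, states6, n_perm = 100, seed = 1),
    "Dropping 1")
  expect_equal(attr(m, "n_subjects"), 4L)
  expect_warning(
    permutation_group_test(array(rnorm(3 * 2 * 6), c(3, 2, 6)),
                           cats6, states6, n_perm = 50, seed = 1),
    "n_perm")
})

test_that("sign-flip paired contrasts control the family-wise error", {
  set.seed(15)
  diffs <- matrix(rnorm(12 * 10), 12, 10)
  diffs[, 2] <- diffs[, 2] + 2
  m <- permutation_paired_contrast(diffs, n_perm = 500, seed = 6)
  expect_true(m$significant[2])
  expect_true(all(m$p_fwer >= m$p_unc))
  expect_gt(m$t[2], 0)
})
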