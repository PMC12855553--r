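test_that("condition matrices are exactly 38 x 405 and block-aligned", {
  des <- build_block_design(blocks_per_condition = 3L, seed = 5)
  mont <- build_montage()
  amp <- matrix(0.5, 38, 6, dimnames = list(NULL, six_conditions))
  rec <- simulate_subject(des, mont, effect_map(amp), noise_spec(),
                          seed = 3)$recording
  m <- extract_condition_matrix(rec, des, "dynamic-anger", subject = "s1")
  expect_equal(dim(m$values), c(38L, 405L))
  on <- des$blocks$onset[des$blocks$condition == "dynamic-anger"][1]
  expect_equal(m$values[, 1], rec$data[, round(on * 10) + 1, 1])
  # constant recordings give constant matrices
  recc <- rec; recc$data[] <- 2
  mc <- extract_condition_matrix(recc, des, "static-neutral")
  expect_true(all(mc$values == 2))
  # per-block mode returns three aligned 38 x 135 slabs
  blocks <- extract_block_matrices(rec, des, "dynamic-anger")
  expect_length(blocks, 3L)
  expect_equal(dim(blocks[[1]]$values), c(38L, 135L))
  expect_equal(cbind(blocks[[1]]$values, blocks[[2]]$values,
                     blocks[[3]]$values), m$values)
})

test_that("the shape contract rejects wrong rates and too few blocks", {
  des <- build_block_design(blocks_per_condition = 3L, seed = 5)
  rec <- matrix_recording(matrix(0, 38, round(des$total_duration * 10)))
  rec$fs <- 20
  expect_error(extract_condition_matrix(rec, des, "dynamic-anger"), "10 Hz")
  des1 <- tiny_design()
  rec1 <- matrix_recording(matrix(0, 38, round(des1$total_duration * 10)))
  expect_error(extract_condition_matrix(rec1, des1, "dynamic-anger"),
               "3 are required")
})

test_that("normalisation cleans outliers and maps channels onto [0, 1]", {
  set.seed(41)
  m <- matrix(rnorm(38 * 405), 38, 405)
  m[1, ] <- seq(0, 1, length.out = 405)       # already a unit ramp
  m[2, 200] <- 10 * sd(m[2, ])                # a gross outlier
  out <- normalize_and_clean(m)
  expect_equal(unname(apply(out, 1, min)), rep(0, 38))
  expect_equal(unname(apply(out, 1, max)), rep(1, 38))
  expect_equal(out[1, ], seq(0, 1, length.out = 405))
  # the outlier was interpolated away before scaling
  neigh <- out[2, c(190:199, 201:210)]
  expect_lt(abs(out[2, 200] - mean(neigh)), 2 * sd(out[2, ]))
  # constant channels cannot be scaled
  m[3, ] <- 7
  expect_warning(out2 <- normalize_and_clean(m), "constant")
  expect_true(all(out2[3, ] == 0))
})

test_that("contrast samples carry the construction labels and counts", {
  trials <- fake_condition_trials(sprintf("sub-%02d", 1:53))
  samples <- build_contrast_samples(trials)
  expect_equal(nrow(samples), 53L * 4L)
  dyn <- samples[samples$modality == "dynamic", ]
  expect_equal(sum(dyn$emotion == "anger"), 53L)
  expect_equal(sum(dyn$emotion == "happiness"), 53L)
  expect_true(all(samples$label[samples$emotion == "anger"] == 0L))
  expect_true(all(samples$label[samples$emotion == "happiness"] == 1L))
  # emotion matrix == neutral matrix -> all-zero sample
  t2 <- trials[trials$subject == "sub-01", ]
  t2$values[t2$condition == "dynamic-anger"] <-
    t2$values[t2$condition == "dynamic-neutral"]
  z <- build_contrast_samples(t2)
  expect_true(all(z$values[[which(z$pair == "dynamic-anger")]] == 0))
  # antisymmetry: swapping emotion and neutral negates the contrast
  t3 <- trials[trials$subject == "sub-02", ]
  t3s <- t3
  ia <- which(t3$condition == "dynamic-anger")
  ine <- which(t3$condition == "dynamic-neutral")
  t3s$values[c(ia, ine)] <- t3$values[c(ine, ia)]
  c1 <- build_contrast_samples(t3); c2 <- build_contrast_samples(t3s)
  k <- which(c1$pair == "dynamic-anger")
  expect_equal(c2$values[[k]], -c1$values[[k]])
  # incomplete subjects are skipped with a message
  expect_message(few <- build_contrast_samples(trials[-1, ]), "sub-01")
  expect_equal(nrow(few), 52L * 4L)
})

test_that("splits respect the 4:1 ratio, folds and determinism", {
  samples <- separable_samples(50)          # 100 samples
  sp <- split_and_fold(samples, seed = 8, grouping = "sample")
  expect_length(sp$test_idx, 20L)
  expect_length(sp$train_idx, 80L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  expect_equal(sort(unique(sp$fold)), 1:5)
  expect_identical(split_and_fold(samples, seed = 8, grouping = "sample"), sp)
  expect_false(identical(split_and_fold(samples, seed = 9,
                                        grouping = "sample")$test_idx,
                         sp$test_idx))
  # test split is label-stratified
  expect_equal(sum(samples$label[sp$test_idx] == 0), 10L)
})

test_that("subject-wise grouping prevents leakage", {
  trials <- fake_condition_trials(sprintf("sub-%02d", 1:20))
  samples <- build_contrast_samples(trials)
  sp <- split_and_fold(samples, seed = 2, grouping = "subject")
  expect_length(intersect(samples$subject[sp$train_idx],
                          samples$subject[sp$test_idx]), 0L)
  # folds partition the training subjects
  for (j in 1:5) {
    in_j <- samples$subject[sp$train_idx[sp$fold == j]]
    out_j <- samples$subject[sp$train_idx[sp$fold != j]]
    expect_length(intersect(in_j, out_j), 0L)
  }
})
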