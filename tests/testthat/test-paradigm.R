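test_that("the default block design honours the paradigm structure", {
  des <- build_block_design(blocks_per_condition = 4L, seed = 1)
  task <- des$blocks[des$blocks$condition != "baseline", ]
  expect_true(all(task$duration == 13.5))
  expect_equal(as.vector(table(task$condition)[six_conditions]), rep(4L, 6))
  # every task block holds 8 stimulus events at 1.5 s spacing
  stim <- des$events[des$events$type == "stimulus", ]
  for (i in seq_len(nrow(task))) {
    ev <- stim$onset[stim$onset >= task$onset[i] &
                       stim$onset < task$onset[i] + task$duration[i]]
    expect_length(ev, 8L)
    expect_equal(diff(ev), rep(1.5, 7))
  }
  # blocks are time-ordered and non-overlapping
  expect_true(all(diff(des$blocks$onset) > 0))
  offsets <- des$blocks$onset + des$blocks$duration
  expect_true(all(des$blocks$onset[-1] >= offsets[-nrow(des$blocks)]))
  expect_gte(des$total_duration, max(offsets))
})

test_that("minimal and degenerate patterns behave", {
  des <- build_block_design(contents = "anger", blocks_per_condition = 1L,
                            order_pattern = "AX", seed = 3)
  expect_equal(des$blocks$condition, c("dynamic-anger", "baseline"))
  expect_true(all(diff(des$blocks$onset) > 0))
  expect_error(build_block_design(order_pattern = "AAB"), "unequal")
  expect_error(build_block_design(order_pattern = "XY"), "tokens")
  expect_error(build_block_design(order_pattern = "X"), "task")
})

test_that("designs are deterministic in the seed", {
  d1 <- build_block_design(seed = 42)
  d2 <- build_block_design(seed = 42)
  d3 <- build_block_design(seed = 43)
  expect_identical(d1$blocks, d2$blocks)
  expect_identical(d1$events, d2$events)
  expect_false(identical(d1$blocks$condition, d3$blocks$condition) &&
                 identical(d1$events$onset, d3$events$onset))
})

test_that("condition boxcars are unit-height, on-grid and non-overlapping", {
  des <- tiny_design()
  x <- condition_boxcar(des, "dynamic-anger")
  expect_length(x, round(des$total_duration * des$fs))
  expect_equal(sum(x), 135)                       # 13.5 s x 10 Hz
  expect_setequal(unique(x), c(0, 1))
  # block starts where the boxcar starts
  on <- des$blocks$onset[des$blocks$condition == "dynamic-anger"]
  expect_equal(which(x == 1)[1], round(on * des$fs) + 1L)
  des4 <- build_block_design(blocks_per_condition = 4L, seed = 9)
  total <- Reduce(`+`, lapply(unique(des4$blocks$condition),
                              condition_boxcar, design = des4))
  expect_lte(max(total), 1)
  for (cond in six_conditions) {
    expect_equal(sum(condition_boxcar(des4, cond)), 4 * 13.5 * 10)
  }
  expect_error(condition_boxcar(des, "dynamic-happiness"), "dynamic-anger")
})

test_that("events TSV export is BIDS-shaped", {
  des <- build_block_design(seed = 1)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_events_tsv(des, path)
  tab <- utils::read.delim(path)
  expect_named(tab, c("onset", "duration", "trial_type"))
  expect_true(all(diff(tab$onset) >= 0))
})
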