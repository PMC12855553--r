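#' Generate an alternating block design
#'
#' Builds the stimulus schedule of a block-design run in which dynamic (A) and
#' static (B) presentations of each stimulus content alternate with baseline
#' fixation blocks (X), following a repeating token pattern such as `"ABXBAX"`.
#' Every task block lasts `block_duration_s` seconds, contains
#' `stimuli_per_block` stimulus events separated by `isi_s`, and is preceded by
#' a 1 s fixation cross; the run starts and ends with `lead_s` seconds of
#' fixation. Which content (e.g. anger, happiness, neutral) a given A or B
#' block shows is randomised under `seed`, with each modality-content pair
#' receiving exactly `blocks_per_condition` blocks.
#'
#' @param contents Character vector of stimulus contents
#'   (default `c("anger", "happiness", "neutral")`).
#' @param blocks_per_condition Blocks per modality-content condition. The
#'   decoding protocol uses 3, the activation analysis 4.
#' @param block_duration_s Task/baseline block duration in seconds
#'   (default 13.5).
#' @param order_pattern Token string over `A` (dynamic), `B` (static),
#'   `X` (baseline), cycled until every task condition has its quota.
#' @param fs Sampling rate in Hz; onsets are snapped to this grid.
#' @param seed Integer seed controlling content assignment and probe timing.
#' @param stimuli_per_block,isi_s,stim_duration_s Stimulus events per task
#'   block, inter-stimulus interval (s) and stimulus duration (s).
#' @param pre_block_fixation_s Fixation before each task block (s).
#' @param lead_s Lead-in/lead-out fixation (s).
#' @param star_probes If `TRUE`, an attention star probe (1.5 s) is placed at
#'   a random stimulus slot in half the task blocks; probes carry no
#'   regressor.
#' @return An object of class `nirs_block_design` with elements `blocks`
#'   (tibble: condition, modality, content, onset, duration), `events`
#'   (tibble: onset, duration, type), `fs`, `total_duration`.
#' @export
build_block_design <- function(contents = c("anger", "happiness", "neutral"),
                               blocks_per_condition = 3L,
                               block_duration_s = 13.5,
                               order_pattern = "ABXBAX",
                               fs = 10,
                               seed = 1L,
                               stimuli_per_block = 8L,
                               isi_s = 1.5,
                               stim_duration_s = 0.48,
                               pre_block_fixation_s = 1.0,
                               lead_s = 16.0,
                               star_probes = TRUE) {
  assert_scalar_number(fs, "fs", positive = TRUE)
  assert_scalar_number(block_duration_s, "block_duration_s", positive = TRUE)
  if (blocks_per_condition < 1L) abort("`blocks_per_condition` must be >= 1.")
  tokens <- strsplit(order_pattern, "")[[1]]
  if (!length(tokens) || !all(tokens %in% c("A", "B", "X"))) {
    abort("`order_pattern` must be a non-empty string over tokens A, B, X.")
  }

  k <- as.integer(blocks_per_condition)
  # Quota per modality: every content gets k blocks in each modality the
  # pattern uses.
  n_a <- if ("A" %in% tokens) length(contents) * k else 0L
  n_b <- if ("B" %in% tokens) length(contents) * k else 0L
  if (n_a + n_b == 0L) abort("`order_pattern` contains no task (A/B) tokens.")
  # Cycle tokens until A and B both hit their quota; overshoot means the
  # pattern cannot give dynamic and static equal block counts.
  seq_tokens <- character(0)
  counts <- c(A = 0L, B = 0L, X = 0L)
  i <- 0L
  repeat {
    if (counts[["A"]] == n_a && counts[["B"]] == n_b) break
    if (counts[["A"]] > n_a || counts[["B"]] > n_b ||
        i > 10L * length(tokens) * (n_a + n_b + 1L)) {
      abort(sprintf(
        "order_pattern '%s' cannot allocate %d blocks to each of the %d task conditions (unequal A/B block counts).",
        order_pattern, k, 2L * length(contents)))
    }
    tok <- tokens[(i %% length(tokens)) + 1L]
    i <- i + 1L
    seq_tokens <- c(seq_tokens, tok)
    counts[[tok]] <- counts[[tok]] + 1L
  }
  # close with any baseline tokens the pattern places after the last task block
  while (tokens[(i %% length(tokens)) + 1L] == "X") {
    seq_tokens <- c(seq_tokens, "X")
    i <- i + 1L
  }

  snap <- function(t) round(t * fs) / fs

  design <- with_seed(seed, {
    content_a <- sample(rep(contents, k))
    content_b <- sample(rep(contents, k))
    ia <- 0L; ib <- 0L
    t <- lead_s
    blocks <- vector("list", length(seq_tokens))
    events <- list()
    for (j in seq_along(seq_tokens)) {
      tok <- seq_tokens[j]
      if (tok == "X") {
        onset <- snap(t)
        blocks[[j]] <- tibble(condition = "baseline", modality = "baseline",
                              content = "neutral-fixation", onset = onset,
                              duration = block_duration_s)
        t <- onset + block_duration_s
      } else {
        modality <- if (tok == "A") "dynamic" else "static"
        content <- if (tok == "A") {
          ia <- ia + 1L; content_a[ia]
        } else {
          ib <- ib + 1L; content_b[ib]
        }
        t <- t + pre_block_fixation_s
        onset <- snap(t)
        blocks[[j]] <- tibble(condition = paste(modality, content, sep = "-"),
                              modality = modality, content = content,
                              onset = onset, duration = block_duration_s)
        stim_onsets <- onset + (seq_len(stimuli_per_block) - 1L) * isi_s
        events[[length(events) + 1L]] <-
          tibble(onset = stim_onsets, duration = stim_duration_s,
                 type = "stimulus",
                 trial_type = paste(modality, content, sep = "-"))
        if (star_probes && runif(1) < 0.5) {
          slot <- sample.int(stimuli_per_block, 1L)
          events[[length(events) + 1L]] <-
            tibble(onset = stim_onsets[slot], duration = isi_s,
                   type = "star_probe", trial_type = "star")
        }
        t <- onset + block_duration_s
      }
    }
    list(blocks = dplyr::bind_rows(blocks),
         events = dplyr::arrange(dplyr::bind_rows(events), .data$onset))
  })

  total <- max(design$blocks$onset + design$blocks$duration) + lead_s
  structure(list(blocks = design$blocks, events = design$events, fs = fs,
                 total_duration = total,
                 blocks_per_condition = k, contents = contents),
            class = "nirs_block_design")
}

#' @export
print.nirs_block_design <- function(x, ...) {
  cat(sprintf("<nirs_block_design> %d blocks, %.1f s total at %g Hz\n",
              nrow(x$blocks), x$total_duration, x$fs))
  print(table(x$blocks$condition))
  invisible(x)
}

# Task (non-baseline) condition labels present in a design.
task_conditions <- function(design) {
  unique(design$blocks$condition[design$blocks$condition != "baseline"])
}

#' Unit-height boxcar regressor support for one condition
#'
#' @param design A `nirs_block_design`.
#' @param condition A condition label present in the design
#'   (e.g. `"dynamic-anger"` or `"baseline"`).
#' @return Numeric vector of length `round(total_duration * fs)` that is 1
#'   inside the condition's blocks and 0 elsewhere.
#' @export
condition_boxcar <- function(design, condition) {
  stopifnot(inherits(design, "nirs_block_design"))
  valid <- unique(design$blocks$condition)
  if (!condition %in% valid) {
    abort(sprintf("Condition '%s' not in design; valid conditions: %s",
                  condition, paste(valid, collapse = ", ")))
  }
  n <- round(design$total_duration * design$fs)
  x <- numeric(n)
  rows <- design$blocks[design$blocks$condition == condition, ]
  for (j in seq_len(nrow(rows))) {
    start <- round(rows$onset[j] * design$fs) + 1L
    len <- round(rows$duration[j] * design$fs)
    x[start:(start + len - 1L)] <- 1
  }
  x
}

#' Write a BIDS-style events table
#'
#' @param design A `nirs_block_design`.
#' @param path Output TSV path.
#' @param what `"events"` (individual stimuli) or `"blocks"`.
#' @return `path`, invisibly.
#' @export
write_events_tsv <- function(design, path, what = c("events", "blocks")) {
  what <- match.arg(what)
  tab <- if (what == "events") {
    design$events[, c("onset", "duration", "trial_type")]
  } else {
    tibble(onset = design$blocks$onset, duration = design$blocks$duration,
           trial_type = design$blocks$condition)
  }
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
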