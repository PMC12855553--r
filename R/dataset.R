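BLOCK_SAMPLES <- 135L   # 13.5 s at 10 Hz
N_TRIAL_BLOCKS <- 3L
TRIAL_STEPS <- BLOCK_SAMPLES * N_TRIAL_BLOCKS   # 405

#' Extract a condition's 38 x 405 trial matrix
#'
#' Concatenates the first three 13.5 s blocks of one condition (135 samples
#' each at 10 Hz) into a channels x time matrix — the unit of data the
#' decoder consumes. The 10 Hz / 13.5 s shape contract is enforced.
#'
#' @param rec A `nirs_recording` with hemoglobin planes.
#' @param design The `nirs_block_design` the recording follows; defaults to
#'   the one stored in the recording.
#' @param condition Task condition label, e.g. `"dynamic-anger"`.
#' @param chromophore `"HbO"` (default) or `"HbR"`.
#' @param subject Optional subject id carried in the result.
#' @return An object of class `nirs_trial_matrix` with a `values` matrix of
#'   exactly 38 x 405.
#' @export
extract_condition_matrix <- function(rec, design = rec$design, condition,
                                     chromophore = "HbO", subject = NA) {
  stopifnot(inherits(rec, "nirs_recording"),
            inherits(design, "nirs_block_design"))
  if (rec$fs != 10) {
    abort(sprintf("Trial matrices are defined at 10 Hz (38 x 405); recording is at %g Hz.",
                  rec$fs))
  }
  plane <- match(chromophore, rec$planes)
  if (is.na(plane)) abort(sprintf("Recording has no '%s' plane.", chromophore))
  blocks <- design$blocks[design$blocks$condition == condition, ]
  if (nrow(blocks) < N_TRIAL_BLOCKS) {
    abort(sprintf("Condition '%s' has %d block(s); %d are required.",
                  condition, nrow(blocks), N_TRIAL_BLOCKS))
  }
  blocks <- blocks[seq_len(N_TRIAL_BLOCKS), ]
  cols <- unlist(lapply(blocks$onset, function(on) {
    start <- round(on * rec$fs) + 1L
    start:(start + BLOCK_SAMPLES - 1L)
  }))
  values <- rec$data[, cols, plane]
  stopifnot(ncol(values) == TRIAL_STEPS)
  structure(list(values = values, condition = condition,
                 subject = subject, chromophore = chromophore),
            class = "nirs_trial_matrix")
}

#' Per-block trial matrices (38 x 135), for sensitivity checks
#'
#' @inheritParams extract_condition_matrix
#' @return List of `nirs_trial_matrix` objects, one per block, each 38 x 135.
#' @export
extract_block_matrices <- function(rec, design = rec$design, condition,
                                   chromophore = "HbO", subject = NA) {
  full <- extract_condition_matrix(rec, design, condition, chromophore, subject)
  lapply(seq_len(N_TRIAL_BLOCKS), function(b) {
    out <- full
    out$values <- full$values[, ((b - 1L) * BLOCK_SAMPLES + 1L):(b * BLOCK_SAMPLES)]
    out
  })
}

#' Outlier removal and per-channel min-max normalisation
#'
#' Samples beyond `sd_threshold` standard deviations from their channel mean
#' are replaced by linear interpolation of the neighbouring retained samples;
#' each channel is then scaled to the [0, 1] range. A constant channel cannot
#' be scaled and is mapped to zeros with a warning.
#'
#' @param m An `nirs_trial_matrix` (or plain matrix).
#' @param sd_threshold Outlier threshold in channel standard deviations
#'   (default 3).
#' @return The cleaned, scaled object of the same type.
#' @export
normalize_and_clean <- function(m, sd_threshold = 3.0) {
  is_trial <- inherits(m, "nirs_trial_matrix")
  values <- if (is_trial) m$values else as.matrix(m)
  for (ch in seq_len(nrow(values))) {
    x <- values[ch, ]
    mu <- mean(x); s <- sd(x)
    if (s > 0) {
      out <- abs(x - mu) > sd_threshold * s
      if (any(out) && !all(out)) {
        keep <- which(!out)
        x[out] <- approx(keep, x[keep], xout = which(out), rule = 2)$y
      }
    }
    rng <- range(x)
    if (rng[2] > rng[1]) {
      x <- (x - rng[1]) / (rng[2] - rng[1])
    } else {
      warn(sprintf("Channel %d is constant; scaled to zeros.", ch))
      x <- rep(0, length(x))
    }
    values[ch, ] <- x
  }
  if (is_trial) {
    m$values <- values
    m
  } else {
    values
  }
}

CONTRAST_PAIRS <- tibble(
  pair = c("dynamic-anger", "dynamic-happiness",
           "static-anger", "static-happiness"),
  emotion_condition = c("dynamic-anger", "dynamic-happiness",
                        "static-anger", "static-happiness"),
  neutral_condition = c("dynamic-neutral", "dynamic-neutral",
                        "static-neutral", "static-neutral"),
  modality = c("dynamic", "dynamic", "static", "static"),
  emotion = c("anger", "happiness", "anger", "happiness"),
  label = c(0L, 1L, 0L, 1L))

#' Build labelled emotion-minus-neutral contrast samples
#'
#' For every subject with all six condition matrices present, computes the
#' four contrast pairs — dynamic anger - dynamic neutral, dynamic happiness -
#' dynamic neutral, static anger - static neutral, static happiness - static
#' neutral — each a 38 x 405 difference matrix labelled 0 (anger) or 1
#' (happiness). Subjects missing a condition are skipped with a message.
#'
#' @param trials A list of `nirs_trial_matrix` objects, or a tibble with
#'   columns `subject`, `condition` and a list-column `values`.
#' @return A tibble of class `nirs_contrast_samples` with columns `subject`,
#'   `pair`, `modality`, `emotion`, `label` and list-column `values`.
#' @export
build_contrast_samples <- function(trials) {
  if (is.data.frame(trials)) {
    tab <- as_tibble(trials)
  } else {
    tab <- tibble(
      subject = vapply(trials, function(t) as.character(t$subject), character(1)),
      condition = vapply(trials, function(t) t$condition, character(1)),
      values = lapply(trials, function(t) t$values))
  }
  needed <- unique(c(CONTRAST_PAIRS$emotion_condition,
                     CONTRAST_PAIRS$neutral_condition))
  out <- list()
  for (sub in unique(tab$subject)) {
    rows <- tab[tab$subject == sub, ]
    if (!all(needed %in% rows$condition)) {
      message(sprintf(
        "Subject %s is missing condition(s): %s; skipped.", sub,
        paste(setdiff(needed, rows$condition), collapse = ", ")))
      next
    }
    get_m <- function(cond) rows$values[[match(cond, rows$condition)]]
    for (i in seq_len(nrow(CONTRAST_PAIRS))) {
      p <- CONTRAST_PAIRS[i, ]
      out[[length(out) + 1L]] <- tibble(
        subject = sub, pair = p$pair, modality = p$modality,
        emotion = p$emotion, label = p$label,
        values = list(get_m(p$emotion_condition) - get_m(p$neutral_condition)))
    }
  }
  samples <- dplyr::bind_rows(out)
  structure(samples, class = c("nirs_contrast_samples", class(samples)))
}

#' Stratified train/test split with k-fold assignment
#'
#' Splits samples into training and test pools at `ratio` (default 4:1),
#' stratified by label, then partitions the training pool into `k` folds —
#' all deterministic under `seed`. With `grouping = "subject"` (default) the
#' split and folds operate on subjects so no subject appears on both sides;
#' `grouping = "sample"` randomises individual samples.
#'
#' @param samples An `nirs_contrast_samples` tibble (or any tibble with
#'   `subject` and `label` columns).
#' @param ratio Train:test ratio as a length-2 vector (default `c(4, 1)`).
#' @param k Number of cross-validation folds (default 5).
#' @param seed Integer seed.
#' @param grouping `"subject"` or `"sample"`.
#' @return An object of class `nirs_split_spec` with integer `train_idx`,
#'   `test_idx` and `fold` (fold id per training sample).
#' @export
split_and_fold <- function(samples, ratio = c(4, 1), k = 5L, seed = 1L,
                           grouping = c("subject", "sample")) {
  grouping <- match.arg(grouping)
  n <- nrow(samples)
  frac_test <- ratio[2] / sum(ratio)
  res <- with_seed(seed, {
    if (grouping == "subject") {
      subs <- unique(samples$subject)
      n_test <- max(1L, round(length(subs) * frac_test))
      test_subs <- sample(subs, n_test)
      test_idx <- which(samples$subject %in% test_subs)
      train_idx <- setdiff(seq_len(n), test_idx)
      train_subs <- setdiff(subs, test_subs)
      fold_of_sub <- stats::setNames(
        sample(rep(seq_len(k), length.out = length(train_subs))), train_subs)
      fold <- as.integer(fold_of_sub[samples$subject[train_idx]])
    } else {
      test_idx <- integer(0)
      for (lab in unique(samples$label)) {
        pool <- which(samples$label == lab)
        test_idx <- c(test_idx, sample(pool, max(1L, round(length(pool) * frac_test))))
      }
      test_idx <- sort(test_idx)
      train_idx <- setdiff(seq_len(n), test_idx)
      fold <- integer(length(train_idx))
      for (lab in unique(samples$label)) {
        pool <- which(samples$label[train_idx] == lab)
        fold[pool] <- sample(rep(seq_len(k), length.out = length(pool)))
      }
    }
    list(train_idx = train_idx, test_idx = test_idx, fold = fold)
  })
  for (j in seq_len(k)) {
    labs <- samples$label[res$train_idx[res$fold == j]]
    if (length(unique(samples$label)) > 1 &&
        length(unique(labs)) < length(unique(samples$label))) {
      abort(sprintf("Fold %d lacks a class; use more samples or fewer folds.", j))
    }
  }
  structure(list(train_idx = res$train_idx, test_idx = res$test_idx,
                 fold = res$fold, k = as.integer(k), seed = seed,
                 grouping = grouping, n = n),
            class = "nirs_split_spec")
}

#' @export
print.nirs_split_spec <- function(x, ...) {
  cat(sprintf("<nirs_split_spec> %d train / %d test (%s-wise), %d folds, seed %d\n",
              length(x$train_idx), length(x$test_idx), x$grouping, x$k, x$seed))
  invisible(x)
}

#' Serialise a split specification to JSON
#' @param split An `nirs_split_spec`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_split_json <- function(split, path) {
  jsonlite::write_json(unclass(split), path, auto_unbox = TRUE)
  invisible(path)
}
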