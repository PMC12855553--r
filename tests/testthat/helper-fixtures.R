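# Shared fixtures, all generated in code.

six_conditions <- paste(rep(c("dynamic", "static"), each = 3),
                        c("anger", "happiness", "neutral"), sep = "-")

# A small single-condition design: one dynamic-anger block plus baselines.
tiny_design <- function(fs = 10, seed = 1) {
  build_block_design(contents = "anger", blocks_per_condition = 1L,
                     order_pattern = "AX", fs = fs, seed = seed,
                     star_probes = FALSE)
}

# Wrap a channels x samples matrix as an HbO-only recording.
matrix_recording <- function(m, fs = 10, planes = "HbO") {
  d <- array(0, c(nrow(m), ncol(m), length(planes)))
  for (p in seq_along(planes)) d[, , p] <- m
  nirsdecode:::new_recording(d, planes, fs, "hb")
}

# Random 38 x 405 trial-matrix tibble rows for all six conditions.
fake_condition_trials <- function(subjects, seed = 1) {
  set.seed(seed)
  dplyr::bind_rows(lapply(subjects, function(s) {
    tibble::tibble(subject = s, condition = six_conditions,
                   values = lapply(six_conditions, function(cond) {
                     matrix(runif(38 * 405), 38, 405)
                   }))
  }))
}

# Contrast samples whose class means are separable: label-0 samples carry a
# positive block on the first channels, label-1 on the last ones.
separable_samples <- function(n_per_class = 20, noise_sd = 0.05,
                              n_ch = 38, n_t = 405, seed = 1) {
  set.seed(seed)
  rows <- lapply(seq_len(2 * n_per_class), function(i) {
    lab <- as.integer(i > n_per_class)
    m <- matrix(rnorm(n_ch * n_t, 0, noise_sd), n_ch, n_t)
    ch <- if (lab == 0) 1:6 else (n_ch - 5):n_ch
    m[ch, ] <- m[ch, ] + 1
    tibble::tibble(subject = sprintf("sub-%03d", i), pair = "dynamic-anger",
                   modality = "dynamic", emotion = "anger", label = lab,
                   values = list(m))
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("nirs_contrast_samples", class(out)))
}

# Cached results of the high-SNR decoding benchmark, shared by the decoder
# acceptance checks so each model family sees identical data and splits.
benchmark_cache <- new.env(parent = emptyenv())

benchmark_run <- function(seed, kind) {
  key <- sprintf("metrics_%d_%s", seed, kind)
  if (!is.null(benchmark_cache[[key]])) return(benchmark_cache[[key]])
  skey <- sprintf("samples_%d", seed)
  if (is.null(benchmark_cache[[skey]])) {
    benchmark_cache[[skey]] <- decoding_benchmark(n_subjects = 60L, seed = seed)
  }
  samples <- benchmark_cache[[skey]]
  split <- split_and_fold(samples, seed = seed)
  cfg <- train_config(seed = seed)
  m <- if (kind == "svm") {
    train_baseline("svm", samples, split, model_spec(), cfg)
  } else {
    crossvalidate_and_test(samples, split, model_spec(), cfg, kind = kind)
  }
  benchmark_cache[[key]] <- attr(m, "summary")$accuracy
  benchmark_cache[[key]]
}
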