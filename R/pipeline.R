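#' Run configuration for the end-to-end pipeline
#'
#' Bundles every stage's parameters: cohort simulation, preprocessing, GLM
#' and group inference, dataset construction, and decoder training. All
#' seeds are recorded so re-running a stage reproduces its artifacts.
#'
#' @param out_dir Output directory (created if missing).
#' @param n_subjects Cohort size for the simulate stage.
#' @param seed Master seed.
#' @param blocks_per_condition Blocks per condition: the activation analysis
#'   convention is 4, the decoding convention 3 (default, so both the GLM
#'   and dataset stages can run on one cohort).
#' @param preprocess A [preprocess_config()].
#' @param n_perm,alpha Permutation count and significance level of the group
#'   stage.
#' @param grouping,chromophore Dataset-stage options (see [split_and_fold()]
#'   and [extract_condition_matrix()]).
#' @param model A [model_spec()].
#' @param train A [train_config()].
#' @param effects Effect map used by the simulate stage; defaults to
#'   [benchmark_effect_map()].
#' @param noise A [noise_spec()].
#' @param between_subject_sd Between-subject amplitude SD (uM).
#' @return An object of class `nirs_run_config`.
#' @export
run_config <- function(out_dir,
                       n_subjects = 6L,
                       seed = 1L,
                       blocks_per_condition = 3L,
                       preprocess = preprocess_config(),
                       n_perm = 500L,
                       alpha = 0.05,
                       grouping = "subject",
                       chromophore = "HbO",
                       model = model_spec(),
                       train = train_config(seed = seed),
                       effects = NULL,
                       noise = noise_spec(),
                       between_subject_sd = 0.2) {
  cfg <- structure(list(out_dir = out_dir, n_subjects = as.integer(n_subjects),
                        seed = as.integer(seed),
                        blocks_per_condition = as.integer(blocks_per_condition),
                        preprocess = preprocess, n_perm = as.integer(n_perm),
                        alpha = alpha, grouping = grouping,
                        chromophore = chromophore, model = model,
                        train = train, effects = effects, noise = noise,
                        between_subject_sd = between_subject_sd),
                   class = "nirs_run_config")
  check_bands(cfg$preprocess, fs = 10)
  cfg
}

stage_dir <- function(cfg, stage) file.path(cfg$out_dir, stage)

write_recording_csv <- function(rec, path_prefix) {
  for (p in seq_along(rec$planes)) {
    utils::write.csv(rec$data[, , p],
                     sprintf("%s_%s.csv", path_prefix, rec$planes[p]),
                     row.names = FALSE)
  }
  meta <- list(planes = rec$planes, fs = rec$fs, stage = rec$stage,
               stages = rec$stages, usable = rec$usable)
  jsonlite::write_json(meta, paste0(path_prefix, ".json"), auto_unbox = TRUE)
  invisible(path_prefix)
}

read_recording_csv <- function(path_prefix, design = NULL, montage = NULL) {
  meta <- jsonlite::read_json(paste0(path_prefix, ".json"),
                              simplifyVector = TRUE)
  planes <- meta$planes
  mats <- lapply(planes, function(p) {
    as.matrix(utils::read.csv(sprintf("%s_%s.csv", path_prefix, p)))
  })
  data <- array(0, c(nrow(mats[[1]]), ncol(mats[[1]]), length(planes)))
  for (p in seq_along(planes)) data[, , p] <- mats[[p]]
  new_recording(data, planes, meta$fs, meta$stage, design = design,
                montage = montage, usable = meta$usable,
                stages = meta$stages)
}

provenance_json <- function(cfg, stage, path, extra = list()) {
  prov <- c(list(stage = stage,
                 timestamp = format(Sys.time(), tz = "UTC"),
                 seed = cfg$seed,
                 config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
                 package_version = as.character(utils::packageVersion("nirsdecode")),
                 bandstop = cfg$preprocess$bandstop,
                 threshold_factor = cfg$preprocess$threshold_factor,
                 highpass_cutoff = cfg$preprocess$highpass_cutoff,
                 n_perm = cfg$n_perm),
            extra)
  jsonlite::write_json(prov, path, auto_unbox = TRUE)
  invisible(path)
}

require_artifact <- function(path, stage_needed) {
  if (!file.exists(path)) {
    abort(sprintf("Missing upstream artifact '%s'; run stage '%s' first.",
                  path, stage_needed))
  }
  invisible(path)
}

#' Run the analysis pipeline
#'
#' Executes the requested stage (or all stages in order), exchanging
#' artifacts on disk under `cfg$out_dir`: `simulate` writes per-subject
#' hemoglobin CSVs with ground truth, `preprocess` motion-corrects and
#' filters them, `glm` fits first-level models and the permutation group
#' test, `dataset` builds contrast samples and the split, `train`
#' cross-validates the CNN-LSTM decoder. Every stage writes a provenance
#' JSON echoing the parameters it applied.
#'
#' @param cfg An `nirs_run_config`.
#' @param stage One of `"simulate"`, `"preprocess"`, `"glm"`, `"dataset"`,
#'   `"train"`, `"all"`.
#' @return Invisibly, a named list of artifact paths.
#' @export
run_pipeline <- function(cfg, stage = c("all", "simulate", "preprocess",
                                        "glm", "dataset", "train")) {
  stopifnot(inherits(cfg, "nirs_run_config"))
  stage <- match.arg(stage)
  stages <- if (stage == "all") {
    c("simulate", "preprocess", "glm", "dataset", "train")
  } else {
    stage
  }
  out <- list()
  for (s in stages) out[[s]] <- run_stage(cfg, s)
  invisible(out)
}

run_stage <- function(cfg, stage) {
  dir.create(stage_dir(cfg, stage), recursive = TRUE, showWarnings = FALSE)
  switch(stage,
         simulate = stage_simulate(cfg),
         preprocess = stage_preprocess(cfg),
         glm = stage_glm(cfg),
         dataset = stage_dataset(cfg),
         train = stage_train(cfg))
}

pipeline_design <- function(cfg) {
  build_block_design(blocks_per_condition = cfg$blocks_per_condition,
                     seed = cfg$seed)
}

stage_simulate <- function(cfg) {
  dir <- stage_dir(cfg, "simulate")
  montage <- build_montage()
  design <- pipeline_design(cfg)
  effects <- cfg$effects %||% benchmark_effect_map(montage)
  message(sprintf("[simulate] %d subjects, seed %d", cfg$n_subjects, cfg$seed))
  cohort <- simulate_cohort(cfg$n_subjects, design, montage, effects,
                            between_subject_sd = cfg$between_subject_sd,
                            noise = cfg$noise, seed = cfg$seed)
  for (id in names(cohort)) {
    write_recording_csv(cohort[[id]]$recording, file.path(dir, id))
    truth <- cohort[[id]]$truth
    jsonlite::write_json(
      list(amplitude = truth$amplitude, hbr_ratio = truth$hbr_ratio,
           condition_lag_s = as.list(truth$condition_lag_s), seed = truth$seed),
      file.path(dir, paste0(id, "_truth.json")), auto_unbox = TRUE)
  }
  write_montage_csv(montage, file.path(dir, "montage.csv"))
  write_events_tsv(design, file.path(dir, "events.tsv"))
  write_events_tsv(design, file.path(dir, "blocks.tsv"), what = "blocks")
  provenance_json(cfg, "simulate", file.path(dir, "provenance.json"),
                  list(n_subjects = cfg$n_subjects))
  dir
}

pipeline_subject_ids <- function(cfg) sprintf("sub-%02d", seq_len(cfg$n_subjects))

stage_preprocess <- function(cfg) {
  sim_dir <- stage_dir(cfg, "simulate")
  dir <- stage_dir(cfg, "preprocess")
  design <- pipeline_design(cfg)
  montage <- build_montage()
  message(sprintf("[preprocess] bands %s Hz, motion threshold %.1f, DCT cutoff %.3g Hz",
                  paste(vapply(cfg$preprocess$bandstop,
                               function(b) sprintf("%.2f-%.2f", b[1], b[2]),
                               character(1)), collapse = " & "),
                  cfg$preprocess$threshold_factor,
                  cfg$preprocess$highpass_cutoff))
  for (id in pipeline_subject_ids(cfg)) {
    require_artifact(file.path(sim_dir, paste0(id, ".json")), "simulate")
    rec <- read_recording_csv(file.path(sim_dir, id), design, montage)
    rec <- correct_motion(rec, cfg$preprocess)$recording
    rec <- temporal_filter(rec, cfg$preprocess)
    write_recording_csv(rec, file.path(dir, id))
  }
  provenance_json(cfg, "preprocess", file.path(dir, "provenance.json"))
  dir
}

stage_glm <- function(cfg) {
  pre_dir <- stage_dir(cfg, "preprocess")
  dir <- stage_dir(cfg, "glm")
  design <- pipeline_design(cfg)
  montage <- build_montage()
  X <- build_design_matrix(design)
  conds <- attr(X, "task_regressors")
  message(sprintf("[glm] %d regressors + constant, %d permutations",
                  length(conds), cfg$n_perm))
  betas <- list()
  for (id in pipeline_subject_ids(cfg)) {
    require_artifact(file.path(pre_dir, paste0(id, ".json")), "preprocess")
    rec <- read_recording_csv(file.path(pre_dir, id), design, montage)
    fit <- fit_first_level(rec, X, cfg$chromophore)
    betas[[id]] <- fit$betas[, conds, drop = FALSE]
  }
  arr <- array(NA_real_, c(length(betas), nrow(betas[[1]]), length(conds)),
               dimnames = list(names(betas), NULL, conds))
  for (i in seq_along(betas)) arr[i, , ] <- betas[[i]]
  parts <- strsplit(conds, "-", fixed = TRUE)
  states <- vapply(parts, `[`, character(1), 1)
  categories <- vapply(parts, `[`, character(1), 2)
  map <- permutation_group_test(arr, categories, states,
                                n_perm = cfg$n_perm, alpha = cfg$alpha,
                                seed = cfg$seed)
  write_stat_map_csv(map, file.path(dir, "group_stat_map.csv"), montage)
  provenance_json(cfg, "glm", file.path(dir, "provenance.json"),
                  list(alpha = cfg$alpha))
  dir
}

stage_dataset <- function(cfg) {
  pre_dir <- stage_dir(cfg, "preprocess")
  dir <- stage_dir(cfg, "dataset")
  design <- pipeline_design(cfg)
  montage <- build_montage()
  message(sprintf("[dataset] chromophore %s, %s-wise 4:1 split, %d folds",
                  cfg$chromophore, cfg$grouping, cfg$train$k))
  trials <- dplyr::bind_rows(lapply(pipeline_subject_ids(cfg), function(id) {
    require_artifact(file.path(pre_dir, paste0(id, ".json")), "preprocess")
    rec <- read_recording_csv(file.path(pre_dir, id), design, montage)
    subject_condition_matrices(rec, design, id, cfg$chromophore)
  }))
  samples <- build_contrast_samples(trials)
  split <- split_and_fold(samples, k = cfg$train$k, seed = cfg$seed,
                          grouping = cfg$grouping)
  saveRDS(samples, file.path(dir, "samples.rds"))
  write_split_json(split, file.path(dir, "split.json"))
  manifest <- as_tibble(samples[, c("subject", "pair", "modality", "label")])
  manifest$partition <- ifelse(seq_len(nrow(samples)) %in% split$test_idx,
                               "test", "train")
  manifest$fold <- NA_integer_
  manifest$fold[split$train_idx] <- split$fold
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  provenance_json(cfg, "dataset", file.path(dir, "provenance.json"),
                  list(grouping = cfg$grouping))
  dir
}

stage_train <- function(cfg) {
  ds_dir <- stage_dir(cfg, "dataset")
  dir <- stage_dir(cfg, "train")
  require_artifact(file.path(ds_dir, "samples.rds"), "dataset")
  samples <- readRDS(file.path(ds_dir, "samples.rds"))
  task <- samples[samples$modality == "dynamic", ]
  split <- split_and_fold(task, k = cfg$train$k, seed = cfg$seed,
                          grouping = cfg$grouping)
  message(sprintf("[train] CNN-LSTM: %d filters, %d hidden units, lr %.1e, patience %d",
                  cfg$model$n_filters, cfg$model$hidden_units,
                  cfg$train$learning_rate, cfg$train$patience))
  metrics <- crossvalidate_and_test(task, split, cfg$model, cfg$train)
  utils::write.csv(as.data.frame(metrics), file.path(dir, "metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(attr(metrics, "summary")),
                       file.path(dir, "metrics.json"), auto_unbox = TRUE)
  provenance_json(cfg, "train", file.path(dir, "provenance.json"),
                  list(n_filters = cfg$model$n_filters,
                       hidden_units = cfg$model$hidden_units))
  dir
}
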