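#' Region labels used by the default whole-head prefrontal/motor/visual montage
#'
#' @format Character vector of the six cortical regions covered by the probe
#'   set: frontopolar area (FPA), dorsolateral prefrontal cortex (DLPFC),
#'   ventrolateral prefrontal cortex (VLPFC), premotor and supplementary motor
#'   area (PM&SMA), primary somatosensory cortex (S1) and primary visual
#'   cortex (V1).
#' @export
roi_labels <- c("FPA", "DLPFC", "VLPFC", "PM&SMA", "S1", "V1")

N_CHANNELS <- 38L

#' Default channel-to-region assignment
#'
#' Reads the packaged assignment of the 38 measurement channels (20 sources,
#' 16 detectors, 3 cm separation) to the six regions of interest in both
#' hemispheres. The table is a plausible layout consistent with a bilateral
#' prefrontal/motor/visual probe set; swap in your own CSV with the same
#' columns to match a concrete cap.
#'
#' @return A tibble with columns `channel`, `source`, `detector`, `roi`,
#'   `hemisphere`.
#' @export
default_roi_assignment <- function() {
  path <- system.file("extdata", "default_montage.csv", package = "nirsdecode")
  as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Build and validate an optode montage
#'
#' A montage maps each of the 38 measurement channels to a source, a detector
#' and one region-of-interest label, with a common source-detector separation
#' used by the Beer-Lambert conversion.
#'
#' @param roi_assignment Data frame with columns `channel`, `roi`,
#'   `hemisphere` and optionally `source`, `detector`; must cover channels
#'   1..38 exactly once. Defaults to [default_roi_assignment()].
#' @param separation_cm Source-detector separation in cm (default 3).
#' @return An object of class `nirs_montage`.
#' @export
build_montage <- function(roi_assignment = default_roi_assignment(),
                          separation_cm = 3.0) {
  assert_scalar_number(separation_cm, "separation_cm", positive = TRUE)
  if (!is.data.frame(roi_assignment)) {
    abort("`roi_assignment` must be a data frame.")
  }
  need <- c("channel", "roi", "hemisphere")
  missing_cols <- setdiff(need, names(roi_assignment))
  if (length(missing_cols)) {
    abort(paste0("`roi_assignment` is missing columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  ch <- as.integer(roi_assignment$channel)
  dup <- unique(ch[duplicated(ch)])
  if (length(dup)) {
    abort(sprintf("Duplicate channel id(s) in assignment: %s",
                  paste(dup, collapse = ", ")))
  }
  absent <- setdiff(seq_len(N_CHANNELS), ch)
  if (length(absent)) {
    abort(sprintf("Assignment does not cover channel(s): %s",
                  paste(absent, collapse = ", ")))
  }
  extra <- setdiff(ch, seq_len(N_CHANNELS))
  if (length(extra)) {
    abort(sprintf("Channel id(s) outside 1..%d: %s", N_CHANNELS,
                  paste(extra, collapse = ", ")))
  }
  bad_roi <- setdiff(unique(roi_assignment$roi), roi_labels)
  if (length(bad_roi)) {
    abort(sprintf("Unknown ROI label(s): %s (valid: %s)",
                  paste(bad_roi, collapse = ", "),
                  paste(roi_labels, collapse = ", ")))
  }
  bad_hemi <- setdiff(unique(roi_assignment$hemisphere), c("left", "right"))
  if (length(bad_hemi)) {
    abort(sprintf("`hemisphere` must be 'left' or 'right', got: %s",
                  paste(bad_hemi, collapse = ", ")))
  }
  channels <- as_tibble(roi_assignment)
  if (is.null(channels$source)) channels$source <- ceiling(channels$channel / 2)
  if (is.null(channels$detector)) {
    channels$detector <- ((channels$channel - 1L) %% 16L) + 1L
  }
  channels <- channels[order(channels$channel),
                       c("channel", "source", "detector", "roi", "hemisphere")]
  structure(list(channels = channels, separation_cm = separation_cm),
            class = "nirs_montage")
}

#' Channels belonging to a region of interest
#'
#' @param montage A `nirs_montage`.
#' @param roi ROI name, either `"DLPFC"` (both hemispheres) or
#'   `"DLPFC-left"` style.
#' @return Integer vector of channel ids.
#' @export
roi_channels <- function(montage, roi) {
  stopifnot(inherits(montage, "nirs_montage"))
  parts <- strsplit(roi, "-", fixed = TRUE)[[1]]
  label <- parts[1]
  if (!label %in% roi_labels) {
    abort(sprintf("Unknown ROI '%s' (valid: %s)", label,
                  paste(roi_labels, collapse = ", ")))
  }
  keep <- montage$channels$roi == label
  if (length(parts) > 1L) {
    keep <- keep & montage$channels$hemisphere == parts[2]
  }
  montage$channels$channel[keep]
}

#' @export
print.nirs_montage <- function(x, ...) {
  cat(sprintf("<nirs_montage> %d channels, %d sources, %d detectors, %.1f cm separation\n",
              nrow(x$channels), length(unique(x$channels$source)),
              length(unique(x$channels$detector)), x$separation_cm))
  print(table(x$channels$roi, x$channels$hemisphere))
  invisible(x)
}

#' Write / read a montage as CSV
#'
#' @param montage A `nirs_montage`.
#' @param path Output CSV path.
#' @return `path`, invisibly (writer); a `nirs_montage` (reader).
#' @export
write_montage_csv <- function(montage, path) {
  stopifnot(inherits(montage, "nirs_montage"))
  utils::write.csv(montage$channels, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_montage_csv
#' @param separation_cm Separation to attach when reading.
#' @export
read_montage_csv <- function(path, separation_cm = 3.0) {
  build_montage(utils::read.csv(path, check.names = FALSE), separation_cm)
}
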