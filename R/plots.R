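#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_line geom_hline
#'   facet_wrap labs theme_minimal scale_fill_manual
#' @export
ggplot2::autoplot

#' Plot a group statistic map
#'
#' Channel-wise F (or t) statistics, one facet per effect, significant
#' channels highlighted.
#'
#' @param object An `nirs_group_stat_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.nirs_group_stat_map <- function(object, ...) {
  df <- as.data.frame(object)
  stat_col <- if ("F" %in% names(df)) "F" else "t"
  df$stat <- abs(df[[stat_col]])
  p <- ggplot(df, aes(x = .data$channel, y = .data$stat,
                      fill = .data$significant)) +
    geom_col() +
    scale_fill_manual(values = c(`FALSE` = "grey70", `TRUE` = "firebrick"),
                      name = sprintf("p[FWER] < %.2f", attr(object, "alpha"))) +
    labs(x = "channel", y = stat_col) +
    theme_minimal()
  if ("effect" %in% names(df)) p <- p + facet_wrap(~effect, ncol = 1)
  p
}

#' Plot per-fold decoding metrics
#'
#' @param object An `nirs_metrics`.
#' @param ... Unused.
#' @return A ggplot of per-fold accuracy by model.
#' @export
autoplot.nirs_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(as.data.frame(object),
                            c("accuracy", "recall", "precision", "f1"),
                            names_to = "metric")
  ggplot(df, aes(x = factor(.data$fold), y = .data$value,
                 fill = .data$model)) +
    geom_col(position = "dodge") +
    facet_wrap(~metric) +
    labs(x = "fold", y = NULL) +
    theme_minimal()
}

#' Plot a few channels of a recording
#'
#' @param rec A `nirs_recording`.
#' @param channels Channels to draw (default first 4).
#' @param plane Plane name (default first).
#' @param window_s Optional `c(start, end)` window in seconds.
#' @return A ggplot of the selected traces.
#' @export
plot_recording <- function(rec, channels = 1:4, plane = rec$planes[1],
                           window_s = NULL) {
  stopifnot(inherits(rec, "nirs_recording"))
  p <- match(plane, rec$planes)
  n <- dim(rec$data)[2]
  t <- (seq_len(n) - 1) / rec$fs
  keep <- if (is.null(window_s)) rep(TRUE, n) else
    t >= window_s[1] & t <= window_s[2]
  df <- dplyr::bind_rows(lapply(channels, function(ch) {
    tibble(time = t[keep], value = rec$data[ch, keep, p],
           channel = factor(ch))
  }))
  ggplot(df, aes(x = .data$time, y = .data$value, colour = .data$channel)) +
    geom_line(linewidth = 0.3) +
    labs(x = "time (s)", y = sprintf("%s (uM)", plane)) +
    theme_minimal()
}
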