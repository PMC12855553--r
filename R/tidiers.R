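#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy a first-level GLM fit
#'
#' @param x An `nirs_first_level`.
#' @param ... Unused.
#' @return Tibble with one row per channel and regressor: `channel`, `term`,
#'   `estimate`, `std.error`.
#' @export
tidy.nirs_first_level <- function(x, ...) {
  p <- ncol(x$betas)
  n_ch <- nrow(x$betas)
  se <- matrix(NA_real_, n_ch, p)
  for (ch in seq_len(n_ch)) {
    if (!is.na(x$sigma2[ch])) {
      se[ch, ] <- sqrt(diag(x$xtx_inv[, , ch]) * x$sigma2[ch])
    }
  }
  tibble(channel = rep(seq_len(n_ch), each = p),
         term = rep(colnames(x$betas), n_ch),
         estimate = as.vector(t(x$betas)),
         std.error = as.vector(t(se)))
}

#' @rdname tidy.nirs_first_level
#' @export
glance.nirs_first_level <- function(x, ...) {
  tibble(n_channels = nrow(x$betas), n_usable = sum(x$usable),
         dof = x$dof, mean_phi = mean(x$phi, na.rm = TRUE),
         chromophore = x$chromophore)
}

#' Tidy a group statistic map
#'
#' @param x An `nirs_group_stat_map`.
#' @param ... Unused.
#' @return The underlying tibble, stripped of its class.
#' @export
tidy.nirs_group_stat_map <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @rdname tidy.nirs_group_stat_map
#' @export
glance.nirs_group_stat_map <- function(x, ...) {
  tibble(n_channels = length(unique(x$channel)),
         n_significant = sum(x$significant),
         n_perm = attr(x, "n_perm"), alpha = attr(x, "alpha"))
}

#' Tidy cross-validation metrics
#'
#' @param x An `nirs_metrics`.
#' @param ... Unused.
#' @return Per-fold tibble (`tidy`) or the fold-mean summary (`glance`).
#' @export
tidy.nirs_metrics <- function(x, ...) {
  as_tibble(as.data.frame(x))
}

#' @rdname tidy.nirs_metrics
#' @export
glance.nirs_metrics <- function(x, ...) {
  attr(x, "summary")
}
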