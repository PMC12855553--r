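# Repeated-measures two-way ANOVA F statistics, vectorised over channels.
#
# D: (subjects*cells) x channels matrix, rows subject-major (all cells of
# subject 1, then subject 2, ...). cat_id/state_id: per-cell factor level
# indices (length Q = A*B). Returns a 3 x channels matrix of F values for
# the category main effect, state main effect and interaction, each tested
# against its effect-by-subject error term.
rm_anova_f <- function(D, idx) {
  m <- colMeans(D)
  m_a <- rowsum(D, idx$cat_row) / idx$n_per_cat     # A x C
  m_b <- rowsum(D, idx$state_row) / idx$n_per_state # B x C
  m_ab <- rowsum(D, idx$cell_row) / idx$S           # Q x C
  m_s <- rowsum(D, idx$subj_row) / idx$Q            # S x C
  m_sa <- rowsum(D, idx$sa_row) / idx$B             # (S*A) x C
  m_sb <- rowsum(D, idx$sb_row) / idx$A             # (S*B) x C

  ca <- sweep(m_a, 2, m)                            # centred means
  cb <- sweep(m_b, 2, m)
  cab <- m_ab - m_a[idx$cat_of_cell, , drop = FALSE] -
    m_b[idx$state_of_cell, , drop = FALSE]
  cab <- sweep(cab, 2, m, FUN = function(x, mm) x + mm)

  S <- idx$S; A <- idx$A; B <- idx$B
  ss_a <- S * B * colSums(ca^2)
  ss_b <- S * A * colSums(cb^2)
  ss_ab <- S * colSums(cab^2)

  csa <- m_sa - m_s[idx$subj_of_sa, , drop = FALSE] -
    m_a[idx$cat_of_sa, , drop = FALSE]
  csa <- sweep(csa, 2, m, FUN = function(x, mm) x + mm)
  ss_sa <- B * colSums(csa^2)
  csb <- m_sb - m_s[idx$subj_of_sb, , drop = FALSE] -
    m_b[idx$state_of_sb, , drop = FALSE]
  csb <- sweep(csb, 2, m, FUN = function(x, mm) x + mm)
  ss_sb <- A * colSums(csb^2)

  resid <- D - m_sa[idx$sa_row, , drop = FALSE] - m_sb[idx$sb_row, , drop = FALSE] -
    m_ab[idx$cell_row, , drop = FALSE] + m_a[idx$cat_row, , drop = FALSE] +
    m_b[idx$state_row, , drop = FALSE] + m_s[idx$subj_row, , drop = FALSE]
  resid <- sweep(resid, 2, m)
  ss_res <- colSums(resid^2)

  df_a <- A - 1; df_b <- B - 1; df_ab <- df_a * df_b
  df_sa <- df_a * (S - 1); df_sb <- df_b * (S - 1); df_res <- df_ab * (S - 1)
  eps <- 1e-24
  f_of <- function(ss_eff, df_eff, ss_err, df_err) {
    ifelse(ss_eff < eps, 0, (ss_eff / df_eff) / pmax(ss_err / df_err, eps))
  }
  rbind(category = f_of(ss_a, df_a, ss_sa, df_sa),
        state = f_of(ss_b, df_b, ss_sb, df_sb),
        interaction = f_of(ss_ab, df_ab, ss_res, df_res))
}

build_rm_index <- function(S, categories, states) {
  categories <- as.factor(categories)
  states <- as.factor(states)
  Q <- length(categories)
  A <- nlevels(categories); B <- nlevels(states)
  cat_cell <- as.integer(categories)       # length Q
  state_cell <- as.integer(states)
  subj <- rep(seq_len(S), each = Q)
  cat_row <- rep(cat_cell, S)
  state_row <- rep(state_cell, S)
  cell_row <- rep(seq_len(Q), S)
  sa_row <- (subj - 1L) * A + cat_row
  sb_row <- (subj - 1L) * B + state_row
  list(S = S, A = A, B = B, Q = Q,
       cat_row = cat_row, state_row = state_row, cell_row = cell_row,
       subj_row = subj, sa_row = sa_row, sb_row = sb_row,
       n_per_cat = S * Q / A, n_per_state = S * Q / B,
       cat_of_cell = cat_cell, state_of_cell = state_cell,
       subj_of_sa = rep(seq_len(S), each = A),
       cat_of_sa = rep(seq_len(A), S),
       subj_of_sb = rep(seq_len(S), each = B),
       state_of_sb = rep(seq_len(B), S),
       cat_levels = levels(categories), state_levels = levels(states))
}

#' Group-level factorial permutation test with max-statistic FWER control
#'
#' Per channel, a repeated-measures two-way ANOVA (factors: face category and
#' stimulus state, subjects as the random blocking factor) yields F
#' statistics for both main effects and their interaction. Family-wise error
#' over channels is controlled by max-statistic permutation: in each
#' permutation the cell labels are shuffled within every subject
#' (exchangeable under the null of no condition effect), the maximum F across
#' channels is recorded per effect, and the corrected p-value of a channel is
#' the proportion of permuted maxima at or above its observed F. Uncorrected
#' p-values come from the same per-channel permutation distributions.
#'
#' @param subject_contrasts Numeric array, subjects x channels x cells, of
#'   per-subject per-channel condition summaries (e.g. GLM contrast values).
#'   Subjects containing missing cells are dropped with a message.
#' @param categories,states Factor level of each cell slice along the third
#'   dimension (lengths equal to `dim(subject_contrasts)[3]`).
#' @param n_perm Number of permutations (default 10000).
#' @param alpha Significance level recorded in the result (default 0.05).
#' @param seed Integer seed for the permutation stream.
#' @return An object of class `nirs_group_stat_map`: a tibble with columns
#'   `channel`, `effect`, `F`, `df1`, `df2`, `p_unc`, `p_fwer`,
#'   `significant`, with the permutation settings as attributes.
#' @export
permutation_group_test <- function(subject_contrasts, categories, states,
                                   n_perm = 10000L, alpha = 0.05, seed = 1L) {
  stopifnot(is.array(subject_contrasts), length(dim(subject_contrasts)) == 3)
  d <- dim(subject_contrasts)
  if (length(categories) != d[3] || length(states) != d[3]) {
    abort("`categories` and `states` must label the cells (3rd dimension).")
  }
  if (n_perm < 100) warn("`n_perm` < 100 gives a very coarse permutation p-value.")
  complete <- apply(subject_contrasts, 1, function(s) all(is.finite(s)))
  if (!all(complete)) {
    message(sprintf("Dropping %d subject(s) with missing cells.", sum(!complete)))
    subject_contrasts <- subject_contrasts[complete, , , drop = FALSE]
    d <- dim(subject_contrasts)
  }
  S <- d[1]; C <- d[2]; Q <- d[3]
  if (S < 2) abort("Need at least 2 complete subjects.")
  idx <- build_rm_index(S, categories, states)

  # rows subject-major x cell: D[(s-1)*Q + q, ch]
  D <- matrix(aperm(subject_contrasts, c(3, 1, 2)), S * Q, C)
  f_obs <- rm_anova_f(D, idx)

  cnt_unc <- matrix(0, 3, C)
  cnt_max <- matrix(0, 3, C)
  base <- (seq_len(S) - 1L) * Q
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      rows <- unlist(lapply(base, function(b) b + sample.int(Q)),
                     use.names = FALSE)
      f_perm <- rm_anova_f(D[rows, , drop = FALSE], idx)
      cnt_unc <- cnt_unc + (f_perm >= f_obs)
      mx <- apply(f_perm, 1, max)
      cnt_max <- cnt_max + (mx >= f_obs) * 1
    }
  })
  p_unc <- (cnt_unc + 1) / (n_perm + 1)
  p_fwer <- (cnt_max + 1) / (n_perm + 1)
  p_fwer <- pmax(p_fwer, p_unc)

  S1 <- idx$S; A <- idx$A; B <- idx$B
  df1 <- c(A - 1, B - 1, (A - 1) * (B - 1))
  df2 <- c((A - 1) * (S1 - 1), (B - 1) * (S1 - 1), (A - 1) * (B - 1) * (S1 - 1))
  out <- tibble(
    channel = rep(seq_len(C), each = 3),
    effect = rep(rownames(f_obs), C),
    F = as.numeric(f_obs),
    df1 = rep(df1, C), df2 = rep(df2, C),
    p_unc = as.numeric(p_unc),
    p_fwer = as.numeric(p_fwer))
  out$significant <- out$p_fwer < alpha
  structure(out, n_perm = n_perm, alpha = alpha, seed = seed,
            n_subjects = S1,
            class = c("nirs_group_stat_map", class(out)))
}

#' Paired simple-effect contrast with sign-flip max-statistic correction
#'
#' For a within-subject difference between two conditions, computes the
#' paired t statistic per channel and corrects family-wise error across
#' channels by sign-flipping permutation of the per-subject differences,
#' using the maximum |t| across channels.
#'
#' @param diffs Numeric matrix, subjects x channels, of within-subject
#'   condition differences.
#' @inheritParams permutation_group_test
#' @return A tibble `channel`, `t`, `p_unc`, `p_fwer`, `significant` of class
#'   `nirs_group_stat_map`.
#' @export
permutation_paired_contrast <- function(diffs, n_perm = 10000L, alpha = 0.05,
                                        seed = 1L) {
  stopifnot(is.matrix(diffs))
  S <- nrow(diffs); C <- ncol(diffs)
  if (S < 2) abort("Need at least 2 subjects.")
  t_of <- function(M) {
    mu <- colMeans(M)
    se <- sqrt(apply(M, 2, stats::var) / S)
    ifelse(se == 0, 0, mu / se)
  }
  t_obs <- abs(t_of(diffs))
  cnt_unc <- numeric(C); cnt_max <- numeric(C)
  with_seed(seed, {
    for (i in seq_len(n_perm)) {
      signs <- sample(c(-1, 1), S, replace = TRUE)
      t_perm <- abs(t_of(diffs * signs))
      cnt_unc <- cnt_unc + (t_perm >= t_obs)
      cnt_max <- cnt_max + (max(t_perm) >= t_obs)
    }
  })
  p_unc <- (cnt_unc + 1) / (n_perm + 1)
  p_fwer <- pmax((cnt_max + 1) / (n_perm + 1), p_unc)
  out <- tibble(channel = seq_len(C), t = t_of(diffs),
                p_unc = p_unc, p_fwer = p_fwer,
                significant = p_fwer < alpha)
  structure(out, n_perm = n_perm, alpha = alpha, seed = seed,
            class = c("nirs_group_stat_map", class(out)))
}

#' Export a group statistic map as CSV with provenance
#'
#' @param map A `nirs_group_stat_map`.
#' @param path Output CSV path; a JSON provenance block (seed, n_perm, alpha)
#'   is written next to it with extension `.json`.
#' @param montage Optional `nirs_montage` to add ROI labels.
#' @return `path`, invisibly.
#' @export
write_stat_map_csv <- function(map, path, montage = NULL) {
  tab <- as.data.frame(map)
  if (!is.null(montage)) {
    tab$roi <- paste(montage$channels$roi, montage$channels$hemisphere,
                     sep = "-")[tab$channel]
  }
  utils::write.csv(tab, path, row.names = FALSE)
  prov <- list(n_perm = attr(map, "n_perm"), alpha = attr(map, "alpha"),
               seed = attr(map, "seed"))
  jsonlite::write_json(prov, sub("\\.csv$", ".json", path), auto_unbox = TRUE)
  invisible(path)
}
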