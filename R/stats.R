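# One-way repeated-measures analyses of the replicate x condition outcome
# tables: within-subject ANOVA with partial eta squared, and
# Bonferroni-corrected paired post hoc tests.

#' One-way repeated-measures ANOVA
#'
#' Classical sum-of-squares decomposition for a fully crossed design with
#' replicates (model runs) as subjects and conditions as the within-subject
#' factor: `SS_total = SS_subject + SS_condition + SS_error`, with
#' `F = MS_condition / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom and partial eta squared
#' `SS_condition / (SS_condition + SS_error)`. No sphericity correction is
#' applied.
#'
#' @param table Numeric matrix, rows = subjects (replicates), columns =
#'   conditions; no missing cells.
#' @return List with `F`, `df_effect`, `df_error`, `p`, `partial_eta_sq`,
#'   the three sums of squares, and `degenerate` (`TRUE` with `F = NA`
#'   when the error sum of squares is numerically zero).
#' @export
rm_anova <- function(table) {
  table <- as.matrix(table)
  n <- nrow(table)
  k <- ncol(table)
  if (n < 2L || k < 2L)
    stop("need at least 2 subjects and 2 conditions")
  if (anyNA(table)) stop("no missing cells allowed (fully crossed design)")

  grand <- mean(table)
  ss_subject <- k * sum((rowMeans(table) - grand)^2)
  ss_effect <- n * sum((colMeans(table) - grand)^2)
  ss_total <- sum((table - grand)^2)
  ss_error <- ss_total - ss_subject - ss_effect

  df_effect <- k - 1L
  df_error <- (k - 1L) * (n - 1L)
  scale <- max(ss_total, 1)
  degenerate <- ss_error <= 1e-12 * scale
  f <- if (degenerate) NA_real_ else
    (ss_effect / df_effect) / (ss_error / df_error)
  p <- if (degenerate) NA_real_ else
    stats::pf(f, df_effect, df_error, lower.tail = FALSE)
  eta <- if (ss_effect + ss_error <= 0) 0 else
    ss_effect / (ss_effect + ss_error)

  list(F = f, df_effect = df_effect, df_error = df_error, p = p,
       partial_eta_sq = eta, ss_effect = ss_effect, ss_error = ss_error,
       ss_subject = ss_subject, degenerate = degenerate)
}

#' Bonferroni-corrected pairwise post hoc tests
#'
#' A paired t-test for every pair of conditions, with each p-value
#' multiplied by the number of pairs and capped at 1. Pairs whose
#' within-pair differences have zero variance are reported as degenerate
#' (`t = NA`) rather than producing an infinite statistic.
#'
#' @param table Numeric matrix, rows = subjects, columns = conditions
#'   (column names label the output).
#' @return Data frame with one row per pair: `a`, `b`, `mean_diff`, `t`,
#'   `df`, `p_raw`, `p_adjusted`, `degenerate`.
#' @export
bonferroni_pairwise <- function(table) {
  table <- as.matrix(table)
  k <- ncol(table)
  n <- nrow(table)
  if (k < 2L) stop("need at least 2 conditions")
  labels <- colnames(table)
  if (is.null(labels)) labels <- paste0("cond", seq_len(k))
  pairs <- utils::combn(k, 2L)
  n_pairs <- ncol(pairs)

  rows <- lapply(seq_len(n_pairs), function(j) {
    i1 <- pairs[1L, j]; i2 <- pairs[2L, j]
    d <- table[, i1] - table[, i2]
    if (stats::sd(d) <= 1e-12 * max(abs(d), 1)) {
      data.frame(a = labels[i1], b = labels[i2], mean_diff = mean(d),
                 t = NA_real_, df = n - 1L, p_raw = NA_real_,
                 p_adjusted = NA_real_, degenerate = TRUE)
    } else {
      tt <- stats::t.test(table[, i1], table[, i2], paired = TRUE)
      data.frame(a = labels[i1], b = labels[i2], mean_diff = mean(d),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p_raw = tt$p.value,
                 p_adjusted = min(1, tt$p.value * n_pairs),
                 degenerate = FALSE)
    }
  })
  do.call(rbind, rows)
}
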