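#' Pearson correlation matrix with pairwise deletion
#'
#' Pairwise Pearson correlations between the selected columns, with
#' two-sided p-values and per-pair n (pairwise deletion of missing values).
#' A pair with fewer than 3 complete observations, or involving a constant
#' column, gets `NA` rather than an error.
#'
#' @param table data frame (typically a [measure_table()], possibly
#'   aggregated to subject means).
#' @param columns character vector of column names to correlate.
#' @return a `prl_corr` object: list of symmetric matrices `r`, `p`, `n`
#'   (unit diagonal in `r`).
#' @export
pearson_matrix <- function(table, columns = NULL) {
  if (is.null(columns))
    columns <- intersect(measure_table_columns, names(table))
  columns <- columns[vapply(table[columns], is.numeric, TRUE)]
  k <- length(columns)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  n <- matrix(0L, k, k, dimnames = list(columns, columns))
  diag(r) <- 1
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j <= i) next
    x <- table[[columns[i]]]; y <- table[[columns[j]]]
    ok <- stats::complete.cases(x, y)
    n[i, j] <- n[j, i] <- sum(ok)
    if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) next
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    r[i, j] <- r[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  structure(list(r = r, p = p, n = n), class = "prl_corr")
}

#' @export
print.prl_corr <- function(x, ...) {
  cat("<prl_corr> Pearson correlations (", nrow(x$r), " measures )\n")
  print(round(x$r, 2))
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up FDR adjustment: with ordered p-values `p(1) <= ... <= p(m)`, the
#' adjusted value is `min_{j >= i} m p(j) / j` (capped at 1), and a test is
#' significant at level `q` iff its adjusted p-value is `<= q` —
#' equivalently iff its raw p is at or below the largest `p(k) <= k q / m`.
#' Implemented directly (and cross-checked against `stats::p.adjust` in the
#' tests). `NA` p-values are passed through and never significant.
#'
#' @param pvalues numeric vector of raw p-values in \[0, 1\].
#' @param q FDR level (study: 0.05).
#' @return list with `adjusted` (same length as `pvalues`) and
#'   `significant` (logical).
#' @examples
#' fdr_adjust(c(0.01, 0.02, 0.03, 0.04, 0.9))$significant
#' @export
fdr_adjust <- function(pvalues, q = 0.05) {
  stopifnot(all(is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)))
  adj <- rep(NA_real_, length(pvalues))
  ok <- which(!is.na(pvalues))
  m <- length(ok)
  if (m) {
    o <- order(pvalues[ok])
    ranked <- pvalues[ok][o] * m / seq_len(m)
    adj[ok][o] <- pmin(1, rev(cummin(rev(ranked))))
  }
  list(adjusted = adj, significant = !is.na(adj) & adj <= q)
}

#' Shapiro-Wilk normality screen
#'
#' Runs the Shapiro-Wilk test on each selected column (a precondition check
#' before Pearson correlation). Columns with fewer than 3 non-missing values
#' are skipped with a message; a warning is issued for any column failing at
#' p < 0.05.
#'
#' @inheritParams pearson_matrix
#' @param alpha warning threshold.
#' @return data frame with `measure`, `n`, `W`, `p`.
#' @export
normality_screen <- function(table, columns = NULL, alpha = 0.05) {
  if (is.null(columns))
    columns <- intersect(measure_table_columns, names(table))
  columns <- columns[vapply(table[columns], is.numeric, TRUE)]
  rows <- lapply(columns, function(cl) {
    x <- table[[cl]]
    x <- x[!is.na(x)]
    if (length(x) < 3 || length(unique(x)) == 1) {
      message("normality_screen: skipping '", cl,
              "' (need >= 3 distinct non-missing values)")
      return(data.frame(measure = cl, n = length(x), W = NA_real_,
                        p = NA_real_, stringsAsFactors = FALSE))
    }
    sw <- shapiro.test(x)
    data.frame(measure = cl, n = length(x), W = unname(sw$statistic),
               p = sw$p.value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  bad <- out$measure[!is.na(out$p) & out$p < alpha]
  if (length(bad))
    warning("non-normal measure(s) at Shapiro-Wilk p < ", alpha, ": ",
            paste(bad, collapse = ", "), call. = FALSE)
  out
}

rl_param_columns <- c("alpha_rew", "alpha_nonrew", "beta", "kappa")
conventional_columns <- c("win_stay_correct", "win_stay_incorrect",
                          "lose_shift_correct", "lose_shift_incorrect",
                          "trials_to_criterion", "proportion_correct",
                          "perseverative_responses")

#' Correlate RL parameters with conventional PRL measures
#'
#' The full correlation analysis: optionally aggregate the per-session
#' measure table to per-subject means (the default, matching a
#' subjects-as-units reading of the analysis; set `aggregate = "session"`
#' to use sessions directly), screen all measures with Shapiro-Wilk, compute
#' the Pearson matrix, and apply Benjamini-Hochberg FDR control at level `q`
#' over the unique off-diagonal pairs.
#'
#' @param table a [measure_table()] data frame.
#' @param columns measures to include (default: the four RL parameters and
#'   the seven conventional measures).
#' @param q FDR level.
#' @param aggregate `"subject"` (average sessions within subject) or
#'   `"session"`.
#' @return a `prl_corr` object extended with `p_adj` and `significant`
#'   matrices and the `normality` screen table.
#' @export
correlate_measures <- function(table,
                               columns = c(rl_param_columns,
                                           conventional_columns),
                               q = 0.05,
                               aggregate = c("subject", "session")) {
  aggregate <- match.arg(aggregate)
  if (aggregate == "subject") {
    agg <- stats::aggregate(table[columns],
                            by = list(subject_id = table$subject_id),
                            FUN = function(x) mean(x, na.rm = TRUE))
    agg[columns] <- lapply(agg[columns], function(x) ifelse(is.nan(x), NA, x))
    table <- agg
  }
  normality <- normality_screen(table, columns)
  cm <- pearson_matrix(table, columns)
  ut <- upper.tri(cm$p)
  fdr <- fdr_adjust(cm$p[ut], q)
  p_adj <- sig <- matrix(NA, nrow(cm$p), ncol(cm$p),
                         dimnames = dimnames(cm$p))
  p_adj[ut] <- fdr$adjusted
  sig[ut] <- fdr$significant
  p_adj[lower.tri(p_adj)] <- t(p_adj)[lower.tri(p_adj)]
  sig[lower.tri(sig)] <- t(sig)[lower.tri(sig)]
  cm$p_adj <- p_adj
  cm$significant <- sig
  cm$q <- q
  cm$normality <- normality
  cm
}

#' Tidy export of a correlation analysis
#'
#' @param corr a `prl_corr` from [correlate_measures()].
#' @return data frame with one row per measure pair: `measure1`, `measure2`,
#'   `r`, `p`, `p_adj`, `significant`, `n`.
#' @export
corr_table <- function(corr) {
  ut <- which(upper.tri(corr$r), arr.ind = TRUE)
  nm <- rownames(corr$r)
  data.frame(measure1 = nm[ut[, 1]], measure2 = nm[ut[, 2]],
             r = corr$r[ut], p = corr$p[ut],
             p_adj = if (is.null(corr$p_adj)) NA_real_ else corr$p_adj[ut],
             significant = if (is.null(corr$significant)) NA
                           else corr$significant[ut],
             n = corr$n[ut], stringsAsFactors = FALSE)
}
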