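#' Model-comparison measures
#'
#' Three measures compare the fitted models per session:
#' \describe{
#'   \item{log-likelihood ratio}{`d = 2 (loglik2 - loglik1)`; positive when
#'     model 2 fits better. Antisymmetric under swapping the models.}
#'   \item{pseudo-r2}{`1 - loglik / (n log 0.5)`, the likelihood improvement
#'     over the chance model (P = 0.5 per trial): 0 at chance, 1 at perfect
#'     prediction.}
#'   \item{BIC}{here the log-model-evidence approximation
#'     `loglik - (k/2) log(m)` with `k` free parameters and `m` trials —
#'     larger is better. This is NOT the classical `-2 LL + k log m`
#'     (smaller-is-better) convention; [bic_classic()] converts, and the two
#'     rank models identically (classical = -2 x this one).}
#' }
#'
#' @param fit1,fit2 `prl_fit` objects (or lists with `loglik`, `n_trials`,
#'   `n_free`, `meta`) for the same session.
#' @return `loglik_ratio()`: the scalar d.
#' @examples
#' f1 <- list(loglik = -60, n_trials = 100, n_free = 2)
#' f2 <- list(loglik = -55, n_trials = 100, n_free = 4)
#' loglik_ratio(f1, f2)  # 10
#' pseudo_r2(f2)
#' bic_score(f2)
#' @export
loglik_ratio <- function(fit1, fit2) {
  k1 <- fit_key(fit1); k2 <- fit_key(fit2)
  if (!is.null(k1) && !is.null(k2) && !identical(k1, k2))
    stop("fits are for different sessions: ", k1, " vs ", k2, call. = FALSE)
  2 * (fit2$loglik - fit1$loglik)
}

fit_key <- function(fit) {
  if (is.null(fit$meta)) NULL
  else paste(fit$meta$subject_id, fit$meta$phase, fit$meta$session_index,
             sep = "/")
}

#' @rdname loglik_ratio
#' @param fit a `prl_fit` (or list with `loglik` and `n_trials`).
#' @export
pseudo_r2 <- function(fit) {
  stopifnot(fit$n_trials >= 1)
  1 - fit$loglik / (fit$n_trials * log(0.5))
}

#' @rdname loglik_ratio
#' @export
bic_score <- function(fit) {
  stopifnot(fit$n_trials >= 1)
  fit$loglik - (fit$n_free / 2) * log(fit$n_trials)
}

#' @rdname loglik_ratio
#' @return `bic_classic()`: the classical criterion
#'   `-2 loglik + k log(m)` (smaller is better), equal to `-2 * bic_score()`.
#' @export
bic_classic <- function(fit) -2 * bic_score(fit)

#' Per-session model-comparison table
#'
#' For every session, the log-likelihood, pseudo-r2 and BIC of each model
#' plus the pairwise log-likelihood-ratio statistics `d_<M1>_vs_<M2> =
#' 2 (loglik_M2 - loglik_M1)` for consecutive nesting pairs.
#'
#' @param fits data frame from [fit_dataset()] with every session fitted
#'   under every model.
#' @return data frame, one row per session, columns `loglik_<model>`,
#'   `pseudo_r2_<model>`, `bic_<model>` and the pairwise `d` columns.
#' @export
compare_models <- function(fits) {
  models <- unique(fits$model)
  key <- paste(fits$subject_id, fits$phase, fits$session_index, sep = "/")
  rows <- lapply(split(fits, factor(key, levels = unique(key))), function(g) {
    if (!setequal(g$model, models) || nrow(g) != length(models))
      stop("session ", paste(g$subject_id[1], g$phase[1], g$session_index[1],
                             sep = "/"),
           " is missing model fits", call. = FALSE)
    out <- data.frame(subject_id = g$subject_id[1], group = g$group[1],
                      sex = g$sex[1], phase = g$phase[1],
                      session_index = g$session_index[1],
                      n_trials = g$n_trials[1], stringsAsFactors = FALSE)
    for (m in models) {
      r <- g[g$model == m, ]
      f <- list(loglik = r$loglik, n_trials = r$n_trials, n_free = r$n_free)
      out[[paste0("loglik_", m)]] <- r$loglik
      out[[paste0("pseudo_r2_", m)]] <- pseudo_r2(f)
      out[[paste0("bic_", m)]] <- bic_score(f)
    }
    if (length(models) > 1)
      for (i in seq_len(length(models) - 1)) {
        m1 <- models[i]; m2 <- models[i + 1]
        out[[paste0("d_", m1, "_vs_", m2)]] <-
          2 * (g$loglik[g$model == m2] - g$loglik[g$model == m1])
      }
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the winning model
#'
#' Per-session winners by BIC (log-evidence convention, larger is better)
#' and the overall winner by mean BIC across sessions, with the full
#' comparison table attached.
#'
#' @inheritParams compare_models
#' @return list with `winner` (model name), `mean_bic` (named vector),
#'   `per_session` (winner per session) and `table` ([compare_models()]
#'   output).
#' @export
select_model <- function(fits) {
  tab <- compare_models(fits)
  models <- unique(fits$model)
  bic_cols <- paste0("bic_", models)
  bic_mat <- as.matrix(tab[, bic_cols, drop = FALSE])
  mean_bic <- setNames(colMeans(bic_mat), models)
  per_session <- models[max.col(bic_mat, ties.method = "first")]
  list(winner = names(which.max(mean_bic)), mean_bic = mean_bic,
       per_session = data.frame(tab[, c("subject_id", "phase",
                                        "session_index")],
                                winner = per_session,
                                stringsAsFactors = FALSE),
       table = tab)
}
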