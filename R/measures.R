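#' Win-stay and lose-shift percentages
#'
#' `win_stay()` is the percentage of trials on which the animal repeated its
#' previous choice, among trials whose previous trial was rewarded;
#' `lose_shift()` the percentage on which it switched, among trials whose
#' previous trial was unrewarded. Both are split by whether the previous
#' response was correct (chose the then-designated correct stimulus) or
#' incorrect — possible because probabilistic feedback decouples reward from
#' correctness. Returns `NA` when no trial qualifies (empty denominator),
#' never 0.
#'
#' @param session a [prl_session] with at least 2 trials.
#' @param prev_correct condition on the previous response being `"correct"`
#'   or `"incorrect"`.
#' @return percentage in \[0, 100\], or `NA`.
#' @export
win_stay <- function(session, prev_correct = c("correct", "incorrect")) {
  stay_shift(session, match.arg(prev_correct), prev_rewarded = TRUE,
             count_stay = TRUE)
}

#' @rdname win_stay
#' @export
lose_shift <- function(session, prev_correct = c("correct", "incorrect")) {
  stay_shift(session, match.arg(prev_correct), prev_rewarded = FALSE,
             count_stay = FALSE)
}

stay_shift <- function(session, prev_correct, prev_rewarded, count_stay) {
  tr <- session$trials
  n <- nrow(tr)
  if (n < 2) stop("session must have at least 2 trials", call. = FALSE)
  idx <- 2:n
  prev_was_correct <- tr$chosen_side[idx - 1] == tr$correct_side[idx - 1]
  denom <- (tr$rewarded[idx - 1] == as.integer(prev_rewarded)) &
           (prev_was_correct == (prev_correct == "correct"))
  if (!any(denom)) return(NA_real_)
  stayed <- tr$chosen_side[idx] == tr$chosen_side[idx - 1]
  event <- if (count_stay) stayed else !stayed
  100 * sum(event & denom) / sum(denom)
}

# Lengths of completed contingency blocks, derived from the stored
# reversal_index: a block is completed iff a later trial carries a higher
# index (a criterion met on the session's very last trial is undetectable
# from reversal_index alone and is not counted).
completed_block_lengths <- function(trials) {
  ri <- trials$reversal_index
  if (!length(ri)) return(integer())
  r <- rle(ri)
  if (length(r$lengths) < 2) return(integer())
  r$lengths[-length(r$lengths)]
}

#' Mean trials to criterion
#'
#' For each completed reversal, the number of trials from the start of its
#' contingency block through the trial completing the consecutive-correct
#' criterion; the session value is the mean over completed blocks. The first
#' block (before the first reversal) counts as a block. `NA` when the
#' session completes no reversal.
#'
#' @param session a [prl_session].
#' @param include_first_block count the pre-first-reversal block.
#' @return mean trials per achieved reversal, or `NA`.
#' @export
trials_to_criterion <- function(session, include_first_block = TRUE) {
  len <- completed_block_lengths(session$trials)
  if (!include_first_block && length(len)) len <- len[-1]
  if (!length(len)) return(NA_real_)
  mean(len)
}

#' Proportion of correct responses
#'
#' Fraction of trials on which the chosen side was the currently designated
#' correct side.
#'
#' @param session a non-empty [prl_session].
#' @return fraction in \[0, 1\].
#' @export
proportion_correct <- function(session) {
  tr <- session$trials
  if (nrow(tr) == 0) stop("empty session", call. = FALSE)
  mean(tr$chosen_side == tr$correct_side)
}

#' Perseverative responses after reversals
#'
#' After each contingency reversal, the number of choices of the
#' previously-correct stimulus made before the first choice of the newly
#' correct stimulus, summed over the session's reversals (an
#' average-per-reversal variant is available). In a two-choice task every
#' pre-first-correct choice in a post-reversal block targets the old
#' stimulus.
#'
#' @param session a [prl_session].
#' @param per_reversal if `TRUE`, return the mean per reversal instead of
#'   the session total (`NA` with no reversals; the total is 0).
#' @return count (or mean) of perseverative responses.
#' @export
perseverative_responses <- function(session, per_reversal = FALSE) {
  tr <- session$trials
  ri <- tr$reversal_index
  starts <- which(diff(c(ri[1], ri)) == 1L)   # first trial of each new block
  if (!length(starts)) return(if (per_reversal) NA_real_ else 0L)
  counts <- vapply(starts, function(s) {
    block <- s:nrow(tr)
    block <- block[ri[block] == ri[s]]
    first_new <- which(tr$chosen_side[block] == tr$correct_side[block])[1]
    if (is.na(first_new)) length(block) else first_new - 1L
  }, integer(1))
  if (per_reversal) mean(counts) else sum(counts)
}

#' All conventional PRL measures of one session
#'
#' @param session a [prl_session].
#' @return one-row data frame with `win_stay_correct`, `win_stay_incorrect`,
#'   `lose_shift_correct`, `lose_shift_incorrect`, `trials_to_criterion`,
#'   `proportion_correct` and `perseverative_responses`.
#' @export
conventional_measures <- function(session) {
  data.frame(win_stay_correct = win_stay(session, "correct"),
             win_stay_incorrect = win_stay(session, "incorrect"),
             lose_shift_correct = lose_shift(session, "correct"),
             lose_shift_incorrect = lose_shift(session, "incorrect"),
             trials_to_criterion = trials_to_criterion(session),
             proportion_correct = proportion_correct(session),
             perseverative_responses =
               as.numeric(perseverative_responses(session)))
}

#' Per-session table of RL parameters and conventional measures
#'
#' Joins the `M_a2bk` parameter estimates from a [fit_dataset()] result with
#' the conventional measures of each session: one row per (subject, phase,
#' session), the unit of the correlation analysis and the tidy export a
#' mixed-model analysis would consume.
#'
#' @param sessions list of [prl_session] objects.
#' @param fits data frame from [fit_dataset()]; rows with `model == model`
#'   are used.
#' @param model which model's parameters to report.
#' @return measure-table data frame (see [write_measure_table()]).
#' @export
measure_table <- function(sessions, fits, model = "M_a2bk") {
  f <- fits[fits$model == model, , drop = FALSE]
  rows <- lapply(sessions, function(s) {
    m <- s$meta
    fr <- f[f$subject_id == m$subject_id & f$phase == m$phase &
            f$session_index == m$session_index, , drop = FALSE]
    if (nrow(fr) != 1)
      stop("expected exactly one ", model, " fit for session ",
           session_key(s), call. = FALSE)
    # single-alpha models report their alpha in both slots
    a_rew <- if (is.na(fr$alpha_rew)) fr$alpha else fr$alpha_rew
    a_non <- if (is.na(fr$alpha_nonrew)) fr$alpha else fr$alpha_nonrew
    cbind(data.frame(subject_id = m$subject_id, group = m$group, sex = m$sex,
                     phase = m$phase, session_index = m$session_index,
                     alpha_rew = a_rew, alpha_nonrew = a_non,
                     beta = fr$beta,
                     kappa = if (is.na(fr$kappa)) 0 else fr$kappa,
                     stringsAsFactors = FALSE),
          conventional_measures(s))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
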