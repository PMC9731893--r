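#' @name prl_session
#' @title PRL session objects
#'
#' @description A `prl_session` bundles the subject metadata of one
#' behavioural session with its ordered trials. Trials are stored as a
#' data frame with one row per trial and columns `trial_index` (1-based,
#' consecutive), `chosen_side` and `correct_side` (`"L"`/`"R"`; the correct
#' side is the currently high-probability stimulus), `rewarded` (0/1) and
#' `reversal_index` (0-based count of contingency reversals completed before
#' the trial; non-decreasing, increments by at most 1).
#'
#' @param subject_id character scalar identifying the animal.
#' @param group `"control"` or `"MS"` (maternal separation).
#' @param sex `"female"` or `"male"`.
#' @param phase `"pre_stress"` or `"post_stress"` (before/after the adulthood
#'   stressor).
#' @param session_index 1-based session ordinal within the phase.
#' @param trials data frame of trials as described above; `trial_index` may
#'   be omitted and is then filled in.
#' @return An object of class `prl_session` with elements `meta` (list) and
#'   `trials` (data frame).
#' @examples
#' tr <- data.frame(chosen_side = c("L", "L", "R"),
#'                  correct_side = c("L", "L", "L"),
#'                  rewarded = c(1, 0, 0),
#'                  reversal_index = c(0, 0, 0))
#' s <- prl_session("r1", "control", "female", "pre_stress", 1, tr)
#' n_trials(s)
#' @export
prl_session <- function(subject_id, group, sex, phase, session_index, trials) {
  meta <- list(subject_id = as.character(subject_id),
               group = match.arg(group, c("control", "MS")),
               sex = match.arg(sex, c("female", "male")),
               phase = match.arg(phase, c("pre_stress", "post_stress")),
               session_index = as.integer(session_index))
  trials <- as.data.frame(trials, stringsAsFactors = FALSE)
  if (is.null(trials$trial_index))
    trials$trial_index <- seq_len(nrow(trials))
  trials <- trials[, c("trial_index", "chosen_side", "correct_side",
                       "rewarded", "reversal_index")]
  trials$trial_index <- as.integer(trials$trial_index)
  trials$rewarded <- as.integer(trials$rewarded)
  trials$reversal_index <- as.integer(trials$reversal_index)
  rownames(trials) <- NULL
  problems <- validate_trials(trials)
  if (length(problems))
    stop("invalid trials for session ", meta$subject_id, "/", meta$phase,
         "/", meta$session_index, ": ", paste(problems, collapse = "; "),
         call. = FALSE)
  structure(list(meta = meta, trials = trials), class = "prl_session")
}

# Returns a character vector of violations, each naming the offending
# (1-based) trial row; empty when the trials are valid.
validate_trials <- function(trials) {
  problems <- character()
  n <- nrow(trials)
  if (n == 0) return(problems)
  bad <- which(!trials$chosen_side %in% c("L", "R"))
  if (length(bad))
    problems <- c(problems, paste0("unknown chosen_side at row ", bad[1]))
  bad <- which(!trials$correct_side %in% c("L", "R"))
  if (length(bad))
    problems <- c(problems, paste0("unknown correct_side at row ", bad[1]))
  bad <- which(!trials$rewarded %in% c(0L, 1L))
  if (length(bad))
    problems <- c(problems, paste0("non-binary rewarded at row ", bad[1]))
  if (any(is.na(trials$reversal_index)) || any(trials$reversal_index < 0L)) {
    bad <- which(is.na(trials$reversal_index) | trials$reversal_index < 0L)
    problems <- c(problems, paste0("negative or missing reversal_index at row ",
                                   bad[1]))
  } else if (n > 1) {
    d <- diff(trials$reversal_index)
    bad <- which(d < 0L | d > 1L)
    if (length(bad))
      problems <- c(problems,
                    paste0("non-monotone reversal_index at row ", bad[1] + 1L))
  }
  if (!identical(trials$trial_index, seq_len(n)))
    problems <- c(problems, "trial_index not consecutive from 1")
  problems
}

#' @rdname prl_session
#' @param x,object a `prl_session`.
#' @param ... ignored.
#' @export
print.prl_session <- function(x, ...) {
  m <- x$meta
  cat(sprintf("<prl_session> %s | %s %s | %s session %d | %d trials, %d reversals\n",
              m$subject_id, m$group, m$sex, m$phase, m$session_index,
              nrow(x$trials), max(c(0L, x$trials$reversal_index))))
  invisible(x)
}

#' @rdname prl_session
#' @export
n_trials <- function(object) nrow(object$trials)

#' @rdname prl_session
#' @return `session_key()` returns the `"subject/phase/session"` string that
#'   uniquely identifies a session.
#' @export
session_key <- function(object) {
  m <- object$meta
  paste(m$subject_id, m$phase, m$session_index, sep = "/")
}

session_columns <- c("subject_id", "group", "sex", "phase", "session_index",
                     "trial_index", "chosen_side", "correct_side",
                     "rewarded", "reversal_index")

#' Read and write trial-level session files
#'
#' Sessions are exchanged as comma-separated UTF-8 text with a header and one
#' row per trial, columns `subject_id, group, sex, phase, session_index,
#' trial_index, chosen_side, correct_side, rewarded, reversal_index`. Sides
#' are coded `"L"`/`"R"`, rewards as 0/1. `reversal_index` is stored rather
#' than recomputed on read so that model fitting is insulated from
#' criterion-detection bugs; [check_reversal_index()] recomputes and checks
#' it when wanted.
#'
#' @param path file path.
#' @return `read_sessions()`: a list of [prl_session] objects, grouped by
#'   `(subject_id, phase, session_index)` with within-session row order
#'   preserved. Malformed rows raise an error naming the offending data row.
#' @examples
#' s <- simulate_session(agent_params(), task_config(), seed = 1)
#' f <- tempfile(fileext = ".csv")
#' write_sessions(list(s), f)
#' identical(read_sessions(f)[[1]]$trials, s$trials)
#' @export
read_sessions <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(session_columns, names(df))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  df$.row <- seq_len(nrow(df))
  for (col in c("session_index", "trial_index", "rewarded", "reversal_index")) {
    v <- suppressWarnings(as.integer(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stop("non-integer ", col, " at row ", bad[1], call. = FALSE)
    df[[col]] <- v
  }
  key <- paste(df$subject_id, df$phase, df$session_index, sep = "\r")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(g) {
    g <- g[order(g$trial_index), ]
    problems <- validate_trials(g[, c("trial_index", "chosen_side",
                                      "correct_side", "rewarded",
                                      "reversal_index")])
    if (length(problems)) {
      # map within-session rows back to file data rows
      rowmap <- function(p) {
        m <- regmatches(p, regexpr("[0-9]+$", p))
        if (length(m)) sub("[0-9]+$", g$.row[as.integer(m)], p) else p
      }
      stop("invalid rows in ", path, ": ",
           paste(vapply(problems, rowmap, ""), collapse = "; "),
           call. = FALSE)
    }
    prl_session(g$subject_id[1], g$group[1], g$sex[1], g$phase[1],
                g$session_index[1],
                g[, c("trial_index", "chosen_side", "correct_side",
                      "rewarded", "reversal_index")])
  })
  names(out) <- NULL
  out
}

#' @rdname read_sessions
#' @param sessions list of [prl_session] objects.
#' @return `write_sessions()` invisibly returns `path`. The written file
#'   round-trips through `read_sessions()` losslessly.
#' @export
write_sessions <- function(sessions, path) {
  stopifnot(is.list(sessions))
  rows <- lapply(sessions, function(s) {
    cbind(as.data.frame(s$meta, stringsAsFactors = FALSE)[
            rep(1L, nrow(s$trials)), , drop = FALSE],
          s$trials)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) df <- as.data.frame(setNames(rep(list(character()),
                                                    length(session_columns)),
                                               session_columns))
  rownames(df) <- NULL
  write.csv(df[, session_columns], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Trial and session filters used by the analysis
#'
#' `filter_to_reversals()` keeps, for each session, the prefix of trials up to
#' and including completion of the `max_reversals`-th contingency reversal
#' (trials with `reversal_index < max_reversals`); sessions with fewer
#' reversals are returned whole. `select_sessions()` keeps, per subject and
#' phase, only sessions with `session_index <= per_phase`. The reference analysis
#' uses `max_reversals = 4` and `per_phase = 3`.
#'
#' Both filters are idempotent and commute with each other.
#'
#' @param x a [prl_session] or a list of them.
#' @param max_reversals keep trials up to completion of this reversal.
#' @return filtered object of the same shape as `x`.
#' @export
filter_to_reversals <- function(x, max_reversals = 4) {
  stopifnot(max_reversals >= 1)
  if (inherits(x, "prl_session")) {
    keep <- x$trials$reversal_index < max_reversals
    trials <- x$trials[keep, , drop = FALSE]
    rownames(trials) <- NULL
    m <- x$meta
    return(prl_session(m$subject_id, m$group, m$sex, m$phase,
                       m$session_index, trials))
  }
  lapply(x, filter_to_reversals, max_reversals = max_reversals)
}

#' @rdname filter_to_reversals
#' @param sessions list of [prl_session] objects.
#' @param per_phase maximum session ordinal kept within each subject-phase.
#' @export
select_sessions <- function(sessions, per_phase = 3) {
  stopifnot(per_phase >= 1)
  Filter(function(s) s$meta$session_index <= per_phase, sessions)
}

#' Recompute-and-check validator for stored reversal indices
#'
#' Replays the reversal rule (a reversal after `reversal_criterion`
#' consecutive correct choices; the counter resets on any incorrect choice
#' and on reversal) over a session's choices and compares the recomputed
#' `reversal_index` with the stored one.
#'
#' @param session a [prl_session].
#' @param reversal_criterion consecutive correct choices triggering reversal.
#' @return `TRUE` if the stored indices match; otherwise a character vector
#'   naming the first mismatching trial.
#' @export
check_reversal_index <- function(session, reversal_criterion = 8) {
  tr <- session$trials
  n <- nrow(tr)
  expected <- integer(n)
  streak <- 0L; rev_count <- 0L
  for (t in seq_len(n)) {
    expected[t] <- rev_count
    if (tr$chosen_side[t] == tr$correct_side[t]) {
      streak <- streak + 1L
      if (streak == reversal_criterion) {
        rev_count <- rev_count + 1L
        streak <- 0L
      }
    } else streak <- 0L
  }
  bad <- which(expected != tr$reversal_index)
  if (!length(bad)) return(TRUE)
  paste0("stored reversal_index ", tr$reversal_index[bad[1]],
         " != recomputed ", expected[bad[1]], " at trial ", bad[1])
}

measure_table_columns <- c("subject_id", "group", "sex", "phase",
                           "session_index",
                           "alpha_rew", "alpha_nonrew", "beta", "kappa",
                           "win_stay_correct", "win_stay_incorrect",
                           "lose_shift_correct", "lose_shift_incorrect",
                           "trials_to_criterion", "proportion_correct",
                           "perseverative_responses")

#' Read and write per-session measure tables
#'
#' A measure table has one row per (subject, phase, session) holding the
#' fitted RL parameters and the conventional PRL measures; see
#' [measure_table()]. Files are CSV with missing values written as the
#' explicit sentinel `NA` and a stable column order.
#'
#' @param table measure-table data frame; rows must be uniquely keyed by
#'   (subject_id, phase, session_index).
#' @param path file path.
#' @return `write_measure_table()` invisibly returns `path`;
#'   `read_measure_table()` returns the data frame.
#' @export
write_measure_table <- function(table, path) {
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  missing_cols <- setdiff(measure_table_columns, names(table))
  if (length(missing_cols))
    stop("missing columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  key <- paste(table$subject_id, table$phase, table$session_index)
  if (anyDuplicated(key))
    stop("duplicate session key: ", key[which(duplicated(key))[1]],
         call. = FALSE)
  write.csv(table[, measure_table_columns], path, row.names = FALSE,
            quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_measure_table
#' @export
read_measure_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE, na.strings = "NA")
  df$session_index <- as.integer(df$session_index)
  df
}
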