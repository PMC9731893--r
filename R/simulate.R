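#' Task configuration for the probabilistic reversal learning environment
#'
#' Two stimuli, one designated correct at a time. A correct choice is
#' rewarded with probability `p_reward_correct` (0.8 in the standard task), an
#' incorrect one with `p_reward_incorrect` (0.2). After
#' `reversal_criterion` consecutive correct choices (8) the designation
#' flips; the consecutive-correct counter resets on any incorrect choice and
#' on reversal (by default a correct-but-unrewarded choice does not reset
#' it). Sessions stop at `max_trials` (200); the task's 40-minute clock is
#' not modelled. Setting `p_reward_correct = 1, p_reward_incorrect = 0`
#' recovers the deterministic reversal task.
#'
#' @param p_reward_correct,p_reward_incorrect reward probabilities.
#' @param reversal_criterion consecutive correct choices triggering reversal.
#' @param max_trials session length cap.
#' @param reset_on_unrewarded if `TRUE`, an unrewarded correct choice also
#'   resets the consecutive-correct counter (the criterion's behaviour on
#'   such trials is not pinned down by the task description; the default
#'   counts task-defined correctness only).
#' @return a `prl_task_config` list.
#' @export
task_config <- function(p_reward_correct = 0.8, p_reward_incorrect = 0.2,
                        reversal_criterion = 8, max_trials = 200,
                        reset_on_unrewarded = FALSE) {
  stopifnot(p_reward_incorrect >= 0, p_reward_correct <= 1,
            p_reward_incorrect <= p_reward_correct,
            reversal_criterion >= 1, max_trials >= 1)
  structure(list(p_reward_correct = p_reward_correct,
                 p_reward_incorrect = p_reward_incorrect,
                 reversal_criterion = as.integer(reversal_criterion),
                 max_trials = as.integer(max_trials),
                 reset_on_unrewarded = isTRUE(reset_on_unrewarded)),
            class = "prl_task_config")
}

#' Generative Q-learning agent parameters
#'
#' The simulator's agents choose by the same softmax-with-stickiness rule
#' the models fit ([choice_prob_left()]) and learn by the delta rule
#' ([update_q()]) with separate learning rates after rewarded and
#' non-rewarded trials. Defaults describe a moderately proficient rat:
#' faster learning from rewards than omissions, enough exploitation to reach
#' reversals, mild stickiness.
#'
#' @param alpha_rew,alpha_nonrew learning rates in \[0.001, 1\].
#' @param beta softmax temperature in \[0.005, 5\].
#' @param kappa stickiness in \[-1, 1\].
#' @param q0 initial Q-value for both sides.
#' @return a `prl_agent_params` list.
#' @export
agent_params <- function(alpha_rew = 0.5, alpha_nonrew = 0.3, beta = 0.4,
                         kappa = 0.2, q0 = 0.5) {
  stopifnot(alpha_rew >= 0.001, alpha_rew <= 1,
            alpha_nonrew >= 0.001, alpha_nonrew <= 1,
            beta >= 0.005, beta <= 5, kappa >= -1, kappa <= 1)
  structure(list(alpha_rew = alpha_rew, alpha_nonrew = alpha_nonrew,
                 beta = beta, kappa = kappa, q0 = q0),
            class = "prl_agent_params")
}

#' Simulate one PRL session from a Q-learning agent
#'
#' On each trial the agent chooses L with probability given by
#' [choice_prob_left()] at its current Q-values and previous choice; the
#' reward is Bernoulli with the task's contingency for the chosen side; the
#' chosen side's Q-value is then updated with `alpha_rew` (r = 1) or
#' `alpha_nonrew` (r = 0). Reversals follow the task rules of
#' [task_config()]. Each trial records the pre-trial `reversal_index`, so
#' generated sessions always satisfy the [prl_session] invariants.
#'
#' @param agent [agent_params()].
#' @param task [task_config()].
#' @param meta optional named list overriding subject metadata fields
#'   (`subject_id`, `group`, `sex`, `phase`, `session_index`).
#' @param seed optional integer; when given, seeds the session's RNG stream
#'   (same seed, same session). When `NULL` the current RNG state is used.
#' @return a [prl_session].
#' @export
simulate_session <- function(agent, task = task_config(), meta = list(),
                             seed = NULL) {
  stopifnot(inherits(agent, "prl_agent_params"),
            inherits(task, "prl_task_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- task$max_trials
  chosen <- character(n); correct <- character(n)
  rewarded <- integer(n); rev_index <- integer(n)
  qL <- agent$q0; qR <- agent$q0
  prev <- "none"
  correct_side <- if (runif(1) < 0.5) "L" else "R"
  streak <- 0L; rev_count <- 0L
  for (t in seq_len(n)) {
    pL <- choice_prob_left(qL, qR, agent$beta, agent$kappa, prev)
    ch <- if (runif(1) < pL) "L" else "R"
    is_correct <- ch == correct_side
    p_rew <- if (is_correct) task$p_reward_correct else task$p_reward_incorrect
    r <- as.integer(runif(1) < p_rew)
    chosen[t] <- ch; correct[t] <- correct_side
    rewarded[t] <- r; rev_index[t] <- rev_count
    alpha <- if (r == 1L) agent$alpha_rew else agent$alpha_nonrew
    if (ch == "L") qL <- qL + alpha * (r - qL) else qR <- qR + alpha * (r - qR)
    prev <- ch
    if (is_correct && !(task$reset_on_unrewarded && r == 0L)) {
      streak <- streak + 1L
      if (streak == task$reversal_criterion) {
        correct_side <- if (correct_side == "L") "R" else "L"
        rev_count <- rev_count + 1L
        streak <- 0L
      }
    } else streak <- 0L
  }
  m <- utils::modifyList(list(subject_id = "sim1", group = "control",
                              sex = "female", phase = "pre_stress",
                              session_index = 1L), meta)
  prl_session(m$subject_id, m$group, m$sex, m$phase, m$session_index,
              data.frame(trial_index = seq_len(n), chosen_side = chosen,
                         correct_side = correct, rewarded = rewarded,
                         reversal_index = rev_index,
                         stringsAsFactors = FALSE))
}

#' Cohort design for a stress-by-sex PRL experiment
#'
#' Subjects are arranged in a 2 (control vs MS) x 2 (female vs male) design
#' with `n_per_cell` subjects per cell, each tested `sessions_per_phase`
#' sessions in each phase (before/after adulthood stress). Every
#' (group, sex, phase) cell maps to its own [agent_params()], so group-level
#' shifts in RL parameters (e.g. elevated stickiness in one cell) are stated
#' directly in the design. An optional truncated Gaussian between-subject
#' jitter adds individual variability; the default of no jitter keeps exact
#' ground truth for parameter-recovery tests.
#'
#' @param n_per_cell subjects per (group x sex) cell.
#' @param sessions_per_phase sessions per subject per phase.
#' @param phases which phases to simulate.
#' @param cell_params named list keyed `"<group>.<sex>.<phase>"` of
#'   [agent_params()]; [cell_key()] builds the keys. Missing cells error.
#' @param jitter_sd named numeric vector of between-subject SDs per
#'   parameter (subset of `alpha_rew`, `alpha_nonrew`, `beta`, `kappa`), or
#'   `NULL` for none. Jittered values are truncated to the parameter bounds.
#' @return a `prl_cohort_design` list.
#' @export
cohort_design <- function(n_per_cell = 12, sessions_per_phase = 3,
                          phases = c("pre_stress", "post_stress"),
                          cell_params = default_cell_params(phases),
                          jitter_sd = NULL) {
  stopifnot(n_per_cell >= 1, sessions_per_phase >= 1)
  phases <- match.arg(phases, c("pre_stress", "post_stress"),
                      several.ok = TRUE)
  needed <- as.vector(outer(c("control", "MS"), c("female", "male"),
                            function(g, s) paste(g, s, sep = ".")))
  needed <- as.vector(outer(needed, phases, paste, sep = "."))
  missing_cells <- setdiff(needed, names(cell_params))
  if (length(missing_cells))
    stop("cell_params missing: ", paste(missing_cells, collapse = ", "),
         call. = FALSE)
  structure(list(n_per_cell = as.integer(n_per_cell),
                 sessions_per_phase = as.integer(sessions_per_phase),
                 phases = phases, cell_params = cell_params,
                 jitter_sd = jitter_sd),
            class = "prl_cohort_design")
}

#' @rdname cohort_design
#' @param group,sex,phase cell labels.
#' @export
cell_key <- function(group, sex, phase) paste(group, sex, phase, sep = ".")

#' @rdname cohort_design
#' @export
default_cell_params <- function(phases = c("pre_stress", "post_stress")) {
  keys <- as.vector(outer(
    as.vector(outer(c("control", "MS"), c("female", "male"),
                    function(g, s) paste(g, s, sep = "."))),
    phases, paste, sep = "."))
  setNames(rep(list(agent_params()), length(keys)), keys)
}

# Deterministic child-seed derivation: a small LCG-style integer mix keeping
# everything exactly representable and below 2^31.
child_seed <- function(seed, k) {
  as.integer((as.double(seed) %% 2147483647 * 48271 +
              as.double(k) * 16807 + 12345) %% 2147483647)
}

param_bounds <- list(alpha_rew = c(0.001, 1), alpha_nonrew = c(0.001, 1),
                     beta = c(0.005, 5), kappa = c(-1, 1))

#' Simulate a full cohort
#'
#' Generates `n_per_cell` subjects per (group x sex) cell, each with
#' `sessions_per_phase` sessions per phase, using the cell's agent
#' parameters (optionally jittered once per subject). Each subject draws
#' from its own RNG substream derived from `seed`, so the cohort is
#' reproducible and adding subjects or stages never perturbs earlier
#' streams.
#'
#' @param design [cohort_design()].
#' @param task [task_config()].
#' @param seed master seed (integer).
#' @return list with `sessions` (list of [prl_session]) and `true_params`
#'   (data frame of each subject's generative parameters per phase, for
#'   recovery reports).
#' @export
simulate_cohort <- function(design, task = task_config(), seed = 1) {
  stopifnot(inherits(design, "prl_cohort_design"))
  sessions <- list()
  truth <- list()
  subj_idx <- 0L
  for (group in c("control", "MS")) for (sex in c("female", "male")) {
    for (i in seq_len(design$n_per_cell)) {
      subj_idx <- subj_idx + 1L
      subject_id <- sprintf("%s_%s_%02d", group, sex, i)
      for (phase in design$phases) {
        pars <- design$cell_params[[cell_key(group, sex, phase)]]
        phase_idx <- match(phase, c("pre_stress", "post_stress"))
        sseed <- child_seed(seed, subj_idx * 8L + phase_idx)
        set.seed(sseed)
        if (!is.null(design$jitter_sd)) {
          for (p in names(design$jitter_sd)) {
            b <- param_bounds[[p]]
            pars[[p]] <- min(b[2], max(b[1],
              pars[[p]] + rnorm(1, 0, design$jitter_sd[[p]])))
          }
          pars <- do.call(agent_params, pars[c("alpha_rew", "alpha_nonrew",
                                               "beta", "kappa", "q0")])
        }
        truth[[length(truth) + 1L]] <- data.frame(
          subject_id = subject_id, group = group, sex = sex, phase = phase,
          alpha_rew = pars$alpha_rew, alpha_nonrew = pars$alpha_nonrew,
          beta = pars$beta, kappa = pars$kappa, stringsAsFactors = FALSE)
        for (k in seq_len(design$sessions_per_phase)) {
          sessions[[length(sessions) + 1L]] <- simulate_session(
            pars, task,
            meta = list(subject_id = subject_id, group = group, sex = sex,
                        phase = phase, session_index = k))
        }
      }
    }
  }
  list(sessions = sessions, true_params = do.call(rbind, truth))
}
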