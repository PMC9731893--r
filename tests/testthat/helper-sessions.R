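# Fixture builders and independent oracles shared across test files.

# Build a session directly from trial vectors (reversal_index defaults to 0:
# no reversals).
make_session <- function(chosen, correct, rewarded,
                         reversal = rep(0L, length(chosen)),
                         subject_id = "t1", group = "control",
                         sex = "female", phase = "pre_stress",
                         session_index = 1L) {
  prl_session(subject_id, group, sex, phase, session_index,
              data.frame(trial_index = seq_along(chosen),
                         chosen_side = chosen, correct_side = correct,
                         rewarded = rewarded, reversal_index = reversal,
                         stringsAsFactors = FALSE))
}

# Arbitrary-choice random session (choices and rewards unconstrained by any
# agent; reversal_index recomputed by replaying the criterion rule so the
# stored indices are always valid).
random_session <- function(n = 30, seed = 1, criterion = 8, ...) {
  set.seed(seed)
  chosen <- sample(c("L", "R"), n, replace = TRUE)
  rewarded <- sample(0:1, n, replace = TRUE)
  correct <- character(n)
  side <- "L"; streak <- 0L; rev <- integer(n); rc <- 0L
  for (t in seq_len(n)) {
    correct[t] <- side; rev[t] <- rc
    if (chosen[t] == side) {
      streak <- streak + 1L
      if (streak == criterion) { side <- if (side == "L") "R" else "L"
                                 rc <- rc + 1L; streak <- 0L }
    } else streak <- 0L
  }
  make_session(chosen, correct, rewarded, rev, ...)
}

# Shared toy session for hand-counted conventional measures.
toy6 <- function() make_session(chosen = c("L", "L", "R", "R", "R", "L"),
                                correct = c("L", "L", "R", "R", "R", "R"),
                                rewarded = c(1, 0, 1, 1, 0, 0))

# Independent likelihood oracle: for every trial, recompute the Q trajectory
# from scratch (O(n^2)), evaluate the softmax as the literal exponential
# ratio, and take the log of the literal product of probabilities. Shares no
# code with session_loglik()/cpp_grid_fit().
oracle_loglik <- function(alpha_rew, alpha_nonrew, beta, kappa, session,
                          q0 = 0.5) {
  tr <- session$trials
  n <- nrow(tr)
  prob <- numeric(n)
  for (t in seq_len(n)) {
    qL <- q0; qR <- q0
    if (t > 1) for (u in 1:(t - 1)) {          # replay trials 1..t-1
      a <- if (tr$rewarded[u] == 1) alpha_rew else alpha_nonrew
      if (tr$chosen_side[u] == "L") qL <- qL + a * (tr$rewarded[u] - qL)
      else qR <- qR + a * (tr$rewarded[u] - qR)
    }
    iL <- if (t > 1 && tr$chosen_side[t - 1] == "L") 1 else 0
    iR <- if (t > 1 && tr$chosen_side[t - 1] == "R") 1 else 0
    eL <- exp(qL / beta + kappa * iL)
    eR <- exp(qR / beta + kappa * iR)
    pL <- eL / (eL + eR)
    prob[t] <- if (tr$chosen_side[t] == "L") pL else 1 - pL
  }
  log(prod(prob))
}

# Relabel every L as R and vice versa (choices, correct sides).
swap_sides <- function(session) {
  tr <- session$trials
  flip <- function(x) ifelse(x == "L", "R", "L")
  tr$chosen_side <- flip(tr$chosen_side)
  tr$correct_side <- flip(tr$correct_side)
  m <- session$meta
  prl_session(m$subject_id, m$group, m$sex, m$phase, m$session_index, tr)
}

# Single-phase, single-cell design helper used by several cohort tests.
flat_design <- function(n_per_cell, sessions = 1, pars = agent_params(),
                        jitter_sd = NULL, shift = NULL) {
  cells <- setNames(rep(list(pars), 4),
                    c(cell_key("control", "female", "pre_stress"),
                      cell_key("control", "male", "pre_stress"),
                      cell_key("MS", "female", "pre_stress"),
                      cell_key("MS", "male", "pre_stress")))
  if (!is.null(shift))                      # e.g. list(cell = ..., pars = ...)
    cells[[shift$cell]] <- shift$pars
  cohort_design(n_per_cell = n_per_cell, sessions_per_phase = sessions,
                phases = "pre_stress", cell_params = cells,
                jitter_sd = jitter_sd)
}
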