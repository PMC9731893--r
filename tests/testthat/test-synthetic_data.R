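test_that("config constructors enforce their invariants", {
  expect_error(task_config(p_reward_correct = 0.2, p_reward_incorrect = 0.8))
  expect_error(task_config(reversal_criterion = 0))
  expect_error(agent_params(alpha_rew = 0))
  expect_error(agent_params(beta = 6))
  expect_error(agent_params(kappa = 1.5))
  expect_error(cohort_design(cell_params = list()))  # missing cells
})

test_that("simulate_session is deterministic under a seed", {
  a <- simulate_session(agent_params(), task_config(), seed = 42)
  b <- simulate_session(agent_params(), task_config(), seed = 42)
  expect_identical(a, b)
  c <- simulate_session(agent_params(), task_config(), seed = 43)
  expect_false(identical(a$trials, c$trials))
})

test_that("generated sessions satisfy the trial invariants for random configs", {
  set.seed(8)
  for (i in 1:15) {
    task <- task_config(p_reward_correct = runif(1, 0.5, 1),
                        p_reward_incorrect = runif(1, 0, 0.5),
                        reversal_criterion = sample(2:8, 1),
                        max_trials = sample(20:200, 1))
    agent <- agent_params(alpha_rew = runif(1, 0.1, 1),
                          alpha_nonrew = runif(1, 0.1, 1),
                          beta = runif(1, 0.05, 2),
                          kappa = runif(1, -1, 1))
    s <- simulate_session(agent, task)
    expect_equal(n_trials(s), task$max_trials)
    expect_length(validate_trials(s$trials), 0)
    expect_true(check_reversal_index(s, task$reversal_criterion))
  }
})

test_that("reward contingencies match the task probabilities", {
  # pool correct-choice trials across seeded sessions: empirical reward rate
  # must sit inside 0.78-0.82 around the stated 0.8 contingency
  rewards_correct <- integer(0); rewards_incorrect <- integer(0)
  i <- 0
  while (length(rewards_correct) < 10000) {
    i <- i + 1
    s <- simulate_session(agent_params(), task_config(), seed = 5000 + i)
    corr <- s$trials$chosen_side == s$trials$correct_side
    rewards_correct <- c(rewards_correct, s$trials$rewarded[corr])
    rewards_incorrect <- c(rewards_incorrect, s$trials$rewarded[!corr])
  }
  expect_gt(mean(rewards_correct), 0.78)
  expect_lt(mean(rewards_correct), 0.82)
  expect_gt(mean(rewards_incorrect), 0.17)
  expect_lt(mean(rewards_incorrect), 0.23)
})

test_that("deterministic contingencies reduce to the deterministic task", {
  task <- task_config(p_reward_correct = 1, p_reward_incorrect = 0)
  s <- simulate_session(agent_params(), task, seed = 3)
  corr <- s$trials$chosen_side == s$trials$correct_side
  expect_true(all(s$trials$rewarded[corr] == 1))
  expect_true(all(s$trials$rewarded[!corr] == 0))
})

test_that("a maximally sticky exploit agent nearly always repeats", {
  # kappa = 1 with beta = 0.005: once the previous side has any Q advantage
  # the repeat probability is plogis(gap/0.005 + 1) ~ 1
  expect_gt(choice_prob_left(0.55, 0.5, beta = 0.005, kappa = 1, prev = "L"),
            0.9999)
  expect_equal(choice_prob_left(0.5, 0.5, beta = 0.005, kappa = 1, prev = "L"),
               plogis(1), tolerance = 1e-12)
  s <- simulate_session(agent_params(alpha_rew = 0.5, alpha_nonrew = 0.5,
                                     beta = 0.005, kappa = 1),
                        task_config(), seed = 11)
  rep_rate <- mean(s$trials$chosen_side[-1] ==
                   s$trials$chosen_side[-n_trials(s)])
  expect_gt(rep_rate, 0.9)
})

test_that("simulate_cohort produces the designed session count and labels", {
  design <- cohort_design(n_per_cell = 3, sessions_per_phase = 3)
  sim <- simulate_cohort(design, task_config(max_trials = 30), seed = 2)
  expect_length(sim$sessions, 2 * 2 * 3 * 2 * 3)   # 72
  meta <- do.call(rbind, lapply(sim$sessions, function(s)
    as.data.frame(s$meta, stringsAsFactors = FALSE)))
  expect_setequal(unique(meta$group), c("control", "MS"))
  expect_setequal(unique(meta$phase), c("post_stress", "pre_stress"))
  expect_equal(max(meta$session_index), 3)
  # (subject, phase, session) keys unique
  expect_false(anyDuplicated(meta[c("subject_id", "phase",
                                    "session_index")]) > 0)
  expect_equal(nrow(sim$true_params), 2 * 2 * 3 * 2)
})

test_that("cohorts are reproducible and jitter stays within bounds", {
  design <- flat_design(3, jitter_sd = c(kappa = 0.5, beta = 1))
  a <- simulate_cohort(design, task_config(max_trials = 20), seed = 7)
  b <- simulate_cohort(design, task_config(max_trials = 20), seed = 7)
  expect_identical(a, b)
  expect_true(all(a$true_params$kappa >= -1 & a$true_params$kappa <= 1))
  expect_true(all(a$true_params$beta >= 0.005 & a$true_params$beta <= 5))
  expect_gt(stats::sd(a$true_params$kappa), 0)   # jitter actually applied
  # no jitter: exact cell values as ground truth
  c <- simulate_cohort(flat_design(2), task_config(max_trials = 20), seed = 7)
  expect_true(all(c$true_params$kappa == agent_params()$kappa))
})

test_that("mean win-stay is non-decreasing in kappa on long sessions", {
  kappas <- c(-0.8, 0, 0.8)
  ws <- vapply(seq_along(kappas), function(i) {
    vals <- vapply(1:8, function(j) {
      s <- simulate_session(agent_params(kappa = kappas[i]),
                            task_config(max_trials = 200),
                            seed = 9000 + 100 * i + j)
      mean(c(win_stay(s, "correct"), win_stay(s, "incorrect")), na.rm = TRUE)
    }, 1)
    mean(vals)
  }, 1)
  expect_true(all(diff(ws) > 0))
})
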