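test_that("model specs encode the three variants", {
  expect_equal(model_spec("M_ab")$free, c("alpha", "beta"))
  expect_equal(model_spec("M_abk")$n_free, 3)
  expect_equal(model_spec("M_a2bk")$free,
               c("alpha_rew", "alpha_nonrew", "beta", "kappa"))
  expect_error(model_spec("M_xyz"))
})

test_that("update_q follows the delta rule", {
  expect_equal(update_q(0.5, 0.001, 1), 0.5005)     # near-zero learning
  expect_equal(update_q(0.3, 1, 1), 1)              # full update to r
  expect_equal(update_q(0.5, 0.5, 0), 0.25)         # hand arithmetic
  expect_error(update_q(0.5, 0.5, 0.5))             # non-binary reward
})

test_that("choice_prob_left matches closed-form softmax values", {
  expect_equal(choice_prob_left(0.5, 0.5, beta = 2), 0.5)
  expect_equal(choice_prob_left(0.8, 0.2, beta = 0.6), 1 / (1 + exp(-1)),
               tolerance = 1e-12)
  expect_equal(choice_prob_left(0.5, 0.5, beta = 1, kappa = 0.5, prev = "L"),
               1 / (1 + exp(-0.5)), tolerance = 1e-12)
  expect_error(choice_prob_left(0.5, 0.5, beta = 0), "beta")
  # stability at extreme exponents
  expect_equal(choice_prob_left(1, 0, beta = 0.005), 1, tolerance = 1e-12)
  expect_gt(choice_prob_left(0, 1, beta = 0.005), 0)
})

test_that("P(L) + P(R) = 1 and kappa strictly favours repetition", {
  set.seed(42)
  for (i in 1:50) {
    qL <- runif(1); qR <- runif(1); beta <- runif(1, 0.005, 5)
    kappa <- runif(1, -1, 1)
    prev <- sample(c("none", "L", "R"), 1)
    pL <- choice_prob_left(qL, qR, beta, kappa, prev)
    pR <- choice_prob_left(qR, qL, beta, kappa,
                           switch(prev, none = "none", L = "R", R = "L"))
    expect_equal(pL + pR, 1, tolerance = 1e-12)
  }
  kappas <- seq(-1, 1, by = 0.25)
  p_rep <- vapply(kappas, function(k)
    choice_prob_left(0.4, 0.6, beta = 0.5, kappa = k, prev = "L"), 1)
  expect_true(all(diff(p_rep) > 0))
})

test_that("session_loglik hand-traces on a 2-trial toy session", {
  s <- make_session(c("L", "L"), c("L", "L"), c(1, 0))
  ll <- session_loglik(list(alpha = 0.5, beta = 1, kappa = 0),
                       model_spec("M_abk"), s)
  # trial 1: P = 0.5; trial 2: qL = 0.75, gap 0.25
  expect_equal(ll, log(0.5) + log(1 / (1 + exp(-0.25))), tolerance = 1e-12)
  # with stickiness the second exponent gains kappa
  ll_k <- session_loglik(list(alpha = 0.5, beta = 1, kappa = 0.4),
                         model_spec("M_abk"), s)
  expect_equal(ll_k, log(0.5) + log(1 / (1 + exp(-0.65))), tolerance = 1e-12)
  expect_error(session_loglik(list(alpha = 0.5, beta = 1, kappa = 0),
                              model_spec("M_abk"), make_session(
                                character(), character(), integer())),
               "empty")
  expect_error(session_loglik(list(alpha = 0.5), model_spec("M_abk"),
                              s), "missing parameter")
})

test_that("session_loglik equals the from-scratch literal-product oracle", {
  set.seed(7)
  for (i in 1:20) {
    s <- random_session(30, seed = 1000 + i)
    th <- list(alpha_rew = runif(1, 0.001, 1), alpha_nonrew = runif(1, 0.001, 1),
               beta = runif(1, 0.05, 5), kappa = runif(1, -1, 1))
    ll <- session_loglik(th, model_spec("M_a2bk"), s)
    expect_equal(ll, oracle_loglik(th$alpha_rew, th$alpha_nonrew, th$beta,
                                   th$kappa, s),
                 tolerance = 1e-9)
    expect_lte(ll, 0)
  }
})

test_that("session_loglik is invariant under global L/R relabeling", {
  for (i in 1:5) {
    s <- random_session(40, seed = 2000 + i)
    th <- list(alpha_rew = 0.7, alpha_nonrew = 0.2, beta = 0.35, kappa = -0.3)
    expect_equal(session_loglik(th, model_spec("M_a2bk"), s),
                 session_loglik(th, model_spec("M_a2bk"), swap_sides(s)),
                 tolerance = 1e-12)
  }
})

test_that("model nesting identities hold exactly", {
  s <- random_session(60, seed = 77)
  for (i in 1:5) {
    alpha <- runif(1, 0.001, 1); beta <- runif(1, 0.05, 5)
    kappa <- runif(1, -1, 1)
    ll_a2bk <- session_loglik(list(alpha_rew = alpha, alpha_nonrew = alpha,
                                   beta = beta, kappa = kappa),
                              model_spec("M_a2bk"), s)
    ll_abk <- session_loglik(list(alpha = alpha, beta = beta, kappa = kappa),
                             model_spec("M_abk"), s)
    expect_identical(ll_a2bk, ll_abk)
    ll_abk0 <- session_loglik(list(alpha = alpha, beta = beta, kappa = 0),
                              model_spec("M_abk"), s)
    ll_ab <- session_loglik(list(alpha = alpha, beta = beta),
                            model_spec("M_ab"), s)
    expect_identical(ll_abk0, ll_ab)
  }
})
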