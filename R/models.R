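#' Q-learning model variants
#'
#' Three nested trial-by-trial models of two-choice PRL behaviour:
#' \describe{
#'   \item{`M_ab`}{delta-rule learning with a single learning rate
#'     \eqn{\alpha} and softmax temperature \eqn{\beta}; no stickiness
#'     (\eqn{\kappa} fixed at 0).}
#'   \item{`M_abk`}{adds the choice-autocorrelation ("stickiness") bonus
#'     \eqn{\kappa} for repeating the previous response.}
#'   \item{`M_a2bk`}{splits the learning rate into \eqn{\alpha_{rew}}
#'     (rewarded trials) and \eqn{\alpha_{nonrew}} (non-rewarded trials).}
#' }
#' Parameter ranges: \eqn{\alpha}-type in \[0.001, 1\], \eqn{\beta} in
#' \[0.005, 5\], \eqn{\kappa} in \[-1, 1\].
#'
#' @param name one of `"M_ab"`, `"M_abk"`, `"M_a2bk"`.
#' @return A `prl_model_spec`: list with `name`, `free` (free parameter
#'   names) and `n_free`.
#' @examples
#' model_spec("M_a2bk")$n_free  # 4
#' @export
model_spec <- function(name = c("M_ab", "M_abk", "M_a2bk")) {
  name <- match.arg(name)
  free <- switch(name,
    M_ab = c("alpha", "beta"),
    M_abk = c("alpha", "beta", "kappa"),
    M_a2bk = c("alpha_rew", "alpha_nonrew", "beta", "kappa"))
  structure(list(name = name, free = free, n_free = length(free)),
            class = "prl_model_spec")
}

#' @export
print.prl_model_spec <- function(x, ...) {
  cat(sprintf("<prl_model_spec> %s: {%s} (%d free)\n",
              x$name, paste(x$free, collapse = ", "), x$n_free))
  invisible(x)
}

#' Delta-rule value update
#'
#' `Q <- Q + alpha * (r - Q)`: the chosen option's expected value moves
#' toward the obtained reward by a fraction `alpha` of the prediction error
#' `r - Q`. The unchosen option is not updated and does not decay.
#'
#' @param q current Q-value of the chosen option.
#' @param alpha learning rate in \[0, 1\].
#' @param r reward on the current trial, 0 or 1.
#' @return updated Q-value; stays in \[0, 1\] when `q` starts there.
#' @examples
#' update_q(0.5, 0.5, 0)  # 0.25
#' @export
update_q <- function(q, alpha, r) {
  stopifnot(alpha >= 0, alpha <= 1, r %in% c(0, 1))
  q + alpha * (r - q)
}

#' Softmax choice probability with stickiness
#'
#' Probability of choosing the left option:
#' \deqn{P(L) = \frac{e^{Q(L)/\beta + \kappa L_{t-1}}}
#'   {e^{Q(L)/\beta + \kappa L_{t-1}} + e^{Q(R)/\beta + \kappa R_{t-1}}}}
#' where \eqn{L_{t-1}}, \eqn{R_{t-1}} indicate which side was chosen on the
#' previous trial (both 0 on a session's first trial). Low \eqn{\beta}
#' sharpens preferences (exploitation); high \eqn{\beta} flattens them
#' (exploration). Positive \eqn{\kappa} favours repeating the previous
#' choice regardless of outcome. Computed via the logistic of the exponent
#' difference, so it is numerically stable for extreme arguments.
#'
#' @param q_left,q_right current Q-values of the two options.
#' @param beta softmax temperature, must be > 0.
#' @param kappa stickiness in \[-1, 1\].
#' @param prev previous choice: `"none"`, `"L"` or `"R"`.
#' @return P(choose left); `P(L) + P(R) = 1` by construction.
#' @examples
#' choice_prob_left(0.8, 0.2, beta = 0.6)              # ~0.7311
#' choice_prob_left(0.5, 0.5, beta = 1, kappa = 0.5, prev = "L")  # ~0.6225
#' @export
choice_prob_left <- function(q_left, q_right, beta, kappa = 0,
                             prev = c("none", "L", "R")) {
  if (!is.numeric(beta) || beta <= 0) stop("beta must be > 0", call. = FALSE)
  prev <- match.arg(prev)
  stick <- switch(prev, none = 0, L = 1, R = -1)
  plogis((q_left - q_right) / beta + kappa * stick)
}

# Normalize a params list/vector against a model spec: returns
# c(alpha_rew, alpha_nonrew, beta, kappa) with single-alpha models tied and
# kappa forced to 0 for M_ab.
resolve_params <- function(params, model) {
  p <- as.list(params)
  missing_par <- setdiff(model$free, names(p))
  if (length(missing_par))
    stop("missing parameter(s) for ", model$name, ": ",
         paste(missing_par, collapse = ", "), call. = FALSE)
  if (model$name == "M_a2bk") {
    a1 <- p$alpha_rew; a2 <- p$alpha_nonrew
  } else {
    a1 <- p$alpha; a2 <- p$alpha
  }
  kappa <- if (model$name == "M_ab") 0 else p$kappa
  c(alpha_rew = as.numeric(a1), alpha_nonrew = as.numeric(a2),
    beta = as.numeric(p$beta), kappa = as.numeric(kappa))
}

#' Session log-likelihood of a Q-learning model
#'
#' Walks a session's trials in order, accumulating the log-probability of
#' each observed choice under the softmax rule, then updating the chosen
#' option's Q-value with the trial's reward (using `alpha_rew` when r = 1 and
#' `alpha_nonrew` when r = 0 under `M_a2bk`, the single `alpha` otherwise;
#' `kappa` is fixed at 0 for `M_ab`). This is the log of the product of
#' per-trial choice probabilities; the sum of logs avoids underflow for long
#' sessions. Q-values reset at session start (sessions are fitted
#' independently), and the first trial carries no stickiness.
#'
#' @param params named list/vector with the model's free parameters
#'   (`alpha` or `alpha_rew`/`alpha_nonrew`, `beta`, and `kappa` unless
#'   `M_ab`).
#' @param model a [model_spec()].
#' @param session a [prl_session]; must be non-empty.
#' @param q0 initial Q-value for both sides (default 0.5, the chance
#'   expectation for a 0/1 reward).
#' @return The session log-likelihood (<= 0).
#' @export
session_loglik <- function(params, model, session, q0 = 0.5) {
  tr <- session$trials
  n <- nrow(tr)
  if (n == 0) stop("empty session", call. = FALSE)
  th <- resolve_params(params, model)
  if (th[["beta"]] <= 0) stop("beta must be > 0", call. = FALSE)
  qL <- q0; qR <- q0
  stick <- 0                      # +1 prev L, -1 prev R, 0 none
  ll <- 0
  chose_left <- tr$chosen_side == "L"
  r <- tr$rewarded
  for (t in seq_len(n)) {
    z <- (qL - qR) / th[["beta"]] + th[["kappa"]] * stick
    # log P(observed choice): logistic of +z for L, -z for R
    ll <- ll + plogis(if (chose_left[t]) z else -z, log.p = TRUE)
    alpha <- if (r[t] == 1) th[["alpha_rew"]] else th[["alpha_nonrew"]]
    if (chose_left[t]) qL <- qL + alpha * (r[t] - qL)
    else qR <- qR + alpha * (r[t] - qR)
    stick <- if (chose_left[t]) 1 else -1
  }
  ll
}
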