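#' Parameter grid for grid-search maximum likelihood
#'
#' Each axis is described by `(lower, upper, step)`. Values run `lower,
#' lower + step, lower + 2 step, ...` up to the largest value `<= upper`;
#' the upper bound itself is appended when the last stepped value falls more
#' than half a step short of it, so the documented closed ranges are always
#' honoured. Defaults follow the standard PRL fitting protocol: alpha-type (0.001, 1, 0.05) giving
#' 21 values, beta (0.005, 5, 0.15) giving 34, kappa (-1, 1, 0.1) giving 21.
#'
#' @param alpha,beta,kappa numeric `c(lower, upper, step)` per axis.
#' @param include_upper endpoint rule: `"half_step"` (default, as above),
#'   `"always"`, or `"never"`.
#' @return a `prl_grid_spec` with one `grid_axis()` result per parameter.
#' @examples
#' length(grid_spec()$kappa)  # 21
#' @export
grid_spec <- function(alpha = c(0.001, 1, 0.05),
                      beta = c(0.005, 5, 0.15),
                      kappa = c(-1, 1, 0.1),
                      include_upper = c("half_step", "always", "never")) {
  include_upper <- match.arg(include_upper)
  structure(list(alpha = grid_axis(alpha[1], alpha[2], alpha[3], include_upper),
                 beta = grid_axis(beta[1], beta[2], beta[3], include_upper),
                 kappa = grid_axis(kappa[1], kappa[2], kappa[3], include_upper)),
            class = "prl_grid_spec")
}

#' @rdname grid_spec
#' @param lower,upper,step axis bounds and step; `step > 0`, `lower < upper`.
#' @export
grid_axis <- function(lower, upper, step,
                      include_upper = c("half_step", "always", "never")) {
  include_upper <- match.arg(include_upper)
  stopifnot(step > 0, lower < upper)
  k <- floor((upper - lower) / step + 1e-9)
  v <- lower + step * (0:k)
  v[v > upper] <- upper                       # clamp float spill
  last <- v[length(v)]
  add <- switch(include_upper,
                half_step = (upper - last) > step / 2,
                always = last < upper,
                never = FALSE)
  if (add) v <- c(v, upper)
  v
}

#' Materialize the full parameter grid for a model
#'
#' Cartesian product of the grid axes restricted to the model's free
#' parameters, in lexicographic order (axes ordered `alpha_rew`,
#' `alpha_nonrew`, `alpha`, `beta`, `kappa`; values ascending) — the same
#' order in which [fit_session()] visits grid points and breaks ties.
#'
#' @param grid a [grid_spec()].
#' @param model a [model_spec()].
#' @return data frame with one column per free parameter, one row per grid
#'   point.
#' @export
build_grid <- function(grid = grid_spec(), model) {
  axes <- lapply(model$free, function(p)
    grid[[if (p %in% c("alpha_rew", "alpha_nonrew")) "alpha" else p]])
  names(axes) <- model$free
  # expand.grid varies the first factor fastest; reverse so the first listed
  # axis is the outermost (lexicographic) one
  g <- do.call(expand.grid, c(rev(axes), KEEP.OUT.ATTRS = FALSE))
  g <- g[, rev(seq_along(axes)), drop = FALSE]
  rownames(g) <- NULL
  g
}

#' Grid-search maximum-likelihood fit of one session
#'
#' Evaluates [session_loglik()] at every grid point of the model and returns
#' the maximizing parameters. Ties are broken deterministically by first
#' occurrence in the lexicographic grid order of [build_grid()]. Estimates
#' are grid-quantized; no local refinement is applied.
#'
#' @param session a non-empty [prl_session].
#' @param model a [model_spec()] or model name.
#' @param grid a [grid_spec()].
#' @param q0 initial Q-value for both sides.
#' @return a `prl_fit`: list with `model`, `params` (named list of best-fit
#'   values), `loglik`, `n_trials`, `n_free` and the session `meta`.
#' @examples
#' s <- simulate_session(agent_params(kappa = 0.5), task_config(), seed = 2)
#' fit_session(s, "M_abk")
#' @export
fit_session <- function(session, model, grid = grid_spec(), q0 = 0.5) {
  if (is.character(model)) model <- model_spec(model)
  tr <- session$trials
  if (nrow(tr) == 0) stop("empty session", call. = FALSE)
  code <- match(model$name, c("M_ab", "M_abk", "M_a2bk"))
  kappa_axis <- if (model$name == "M_ab") 0 else grid$kappa
  res <- cpp_grid_fit(as.integer(tr$chosen_side == "L"),
                      as.integer(tr$rewarded),
                      code, grid$alpha, grid$beta, kappa_axis, q0)
  params <- switch(model$name,
    M_ab = list(alpha = res$alpha_rew, beta = res$beta),
    M_abk = list(alpha = res$alpha_rew, beta = res$beta, kappa = res$kappa),
    M_a2bk = list(alpha_rew = res$alpha_rew, alpha_nonrew = res$alpha_nonrew,
                  beta = res$beta, kappa = res$kappa))
  structure(list(model = model, params = params, loglik = res$loglik,
                 n_trials = res$n_trials, n_free = model$n_free,
                 meta = session$meta),
            class = "prl_fit")
}

#' @export
print.prl_fit <- function(x, ...) {
  cat(sprintf("<prl_fit> %s | %s | loglik %.3f over %d trials\n  %s\n",
              paste(x$meta$subject_id, x$meta$phase, x$meta$session_index,
                    sep = "/"),
              x$model$name, x$loglik, x$n_trials,
              paste(names(x$params), signif(unlist(x$params), 4),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @export
as.data.frame.prl_fit <- function(x, ...) {
  p <- x$params
  data.frame(subject_id = x$meta$subject_id, group = x$meta$group,
             sex = x$meta$sex, phase = x$meta$phase,
             session_index = x$meta$session_index,
             model = x$model$name,
             alpha = if (is.null(p$alpha)) NA_real_ else p$alpha,
             alpha_rew = if (is.null(p$alpha_rew)) NA_real_ else p$alpha_rew,
             alpha_nonrew = if (is.null(p$alpha_nonrew)) NA_real_
                            else p$alpha_nonrew,
             beta = p$beta,
             kappa = if (is.null(p$kappa)) NA_real_ else p$kappa,
             loglik = x$loglik, n_trials = x$n_trials, n_free = x$n_free,
             stringsAsFactors = FALSE)
}

#' Fit every session under every model
#'
#' One [fit_session()] per session per model; results are independent of
#' execution order and fully deterministic. Per-session errors are rethrown
#' with the session key attached.
#'
#' @param sessions list of [prl_session] objects.
#' @param models character vector of model names or list of [model_spec()]s.
#' @param grid a [grid_spec()].
#' @param q0 initial Q-value.
#' @param verbose log progress every 10 sessions.
#' @return tidy data frame, one row per session x model, with subject
#'   metadata, parameter estimates (NA for parameters a model lacks),
#'   `loglik`, `n_trials` and `n_free` — the table `compare_models()` and
#'   `measure_table()` consume.
#' @export
fit_dataset <- function(sessions, models = c("M_ab", "M_abk", "M_a2bk"),
                        grid = grid_spec(), q0 = 0.5, verbose = FALSE) {
  if (is.character(models)) models <- lapply(models, model_spec)
  rows <- vector("list", length(sessions) * length(models))
  i <- 0L
  for (si in seq_along(sessions)) {
    s <- sessions[[si]]
    for (m in models) {
      i <- i + 1L
      rows[[i]] <- tryCatch(as.data.frame(fit_session(s, m, grid, q0)),
        error = function(e) stop("session ", session_key(s), ": ",
                                 conditionMessage(e), call. = FALSE))
    }
    if (verbose && si %% 10 == 0)
      message("fitted ", si, "/", length(sessions), " sessions")
  }
  do.call(rbind, rows)
}
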