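#' Run configuration for the end-to-end pipeline
#'
#' Collects everything a reproducible run needs: task parameters, either a
#' cohort design (simulation mode) or a path to an existing trial-log CSV
#' (external-input mode), the fitting grid, the models, the trial/session
#' filters and the FDR level. The master `seed` fully determines all
#' stochastic stages.
#'
#' @param task [task_config()].
#' @param design [cohort_design()], or `NULL` when `input` is given.
#' @param input path to a sessions CSV, or `NULL` to simulate.
#' @param models model names to fit.
#' @param grid [grid_spec()].
#' @param q0 initial Q-value.
#' @param max_reversals trial filter (`NULL` to skip).
#' @param sessions_per_phase session filter (`NULL` to skip).
#' @param fdr_q FDR level for the correlation stage.
#' @param seed master seed.
#' @return a `prl_run_config` list.
#' @export
run_config <- function(task = task_config(), design = cohort_design(),
                       input = NULL, models = c("M_ab", "M_abk", "M_a2bk"),
                       grid = grid_spec(), q0 = 0.5,
                       max_reversals = 4, sessions_per_phase = 3,
                       fdr_q = 0.05, seed = 1) {
  if (is.null(input) && is.null(design))
    stop("need either a cohort design or an input file", call. = FALSE)
  structure(list(task = task, design = design, input = input,
                 models = models, grid = grid, q0 = q0,
                 max_reversals = max_reversals,
                 sessions_per_phase = sessions_per_phase,
                 fdr_q = fdr_q, seed = as.integer(seed)),
            class = "prl_run_config")
}

#' Run the full analysis pipeline
#'
#' simulate (or load) -> filter -> fit -> compare -> conventional measures ->
#' correlate -> recovery report (simulation mode only). Writes
#' `sessions.csv`, `fits.csv`, `comparison.csv`, `measures.csv`, `corr.csv`,
#' `normality.csv`, `recovery.csv` (when ground truth exists) and
#' `manifest.json` (config, package version, seed) into `out_dir`. The same
#' config and seed reproduce every output byte-identically.
#'
#' @param config [run_config()].
#' @param out_dir output directory (created if needed).
#' @param verbose log stage progress.
#' @return invisibly, a list with the in-memory stage results and `out_dir`.
#' @export
run_pipeline <- function(config, out_dir, verbose = FALSE) {
  stopifnot(inherits(config, "prl_run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (verbose) message("[prlqlearn] ", ...)
  stage <- "simulate"
  res <- tryCatch({
    if (is.null(config$input)) {
      say("simulating cohort (seed ", config$seed, ")")
      sim <- simulate_cohort(config$design, config$task, config$seed)
      sessions <- sim$sessions
      true_params <- sim$true_params
    } else {
      say("reading sessions from ", config$input)
      sessions <- read_sessions(config$input)
      true_params <- NULL
    }
    write_sessions(sessions, file.path(out_dir, "sessions.csv"))

    stage <- "filter"
    if (!is.null(config$sessions_per_phase))
      sessions <- select_sessions(sessions, config$sessions_per_phase)
    if (!is.null(config$max_reversals))
      sessions <- filter_to_reversals(sessions, config$max_reversals)
    sessions <- Filter(function(s) nrow(s$trials) > 0, sessions)

    stage <- "fit"
    say("fitting ", length(sessions), " sessions x ",
        length(config$models), " models")
    fits <- fit_dataset(sessions, config$models, config$grid, config$q0,
                        verbose = verbose)
    write.csv(fits, file.path(out_dir, "fits.csv"), row.names = FALSE,
              na = "NA")

    stage <- "compare"
    sel <- select_model(fits)
    write.csv(sel$table, file.path(out_dir, "comparison.csv"),
              row.names = FALSE, na = "NA")
    say("model selected by mean BIC: ", sel$winner)

    stage <- "measures"
    best_model <- if ("M_a2bk" %in% config$models) "M_a2bk" else sel$winner
    mt <- measure_table(sessions, fits, model = best_model)
    write_measure_table(mt, file.path(out_dir, "measures.csv"))

    stage <- "correlate"
    corr <- suppressWarnings(correlate_measures(mt, q = config$fdr_q))
    write.csv(corr_table(corr), file.path(out_dir, "corr.csv"),
              row.names = FALSE, na = "NA")
    write.csv(corr$normality, file.path(out_dir, "normality.csv"),
              row.names = FALSE, na = "NA")

    stage <- "recovery"
    recovery <- NULL
    if (!is.null(true_params)) {
      recovery <- recovery_report(true_params, fits, config$grid,
                                  model = best_model)
      write.csv(recovery, file.path(out_dir, "recovery.csv"),
                row.names = FALSE, na = "NA")
    }

    stage <- "manifest"
    manifest <- list(
      package = "prlqlearn",
      version = as.character(packageVersion("prlqlearn")),
      r_version = as.character(getRversion()),
      seed = config$seed,
      mode = if (is.null(config$input)) "simulation" else "external input",
      models = config$models,
      task = unclass(config$task),
      filters = list(max_reversals = config$max_reversals,
                     sessions_per_phase = config$sessions_per_phase),
      fdr_q = config$fdr_q,
      grid = lapply(unclass(config$grid), as.numeric),
      q0 = config$q0,
      selected_model = sel$winner)
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    list(sessions = sessions, fits = fits, selection = sel,
         measures = mt, corr = corr, recovery = recovery, out_dir = out_dir)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

#' Parameter-recovery report
#'
#' Compares fitted parameters against the simulator's ground truth, per
#' parameter: mean bias (fitted - true), median absolute error in raw units
#' and in grid steps, and the fitted-vs-true Pearson correlation (reported
#' `NA`, not an error, when the truth is constant across subjects). Fitted
#' values are averaged over sessions within subject-phase before comparison.
#'
#' @param true_params data frame of generative parameters
#'   (`simulate_cohort()$true_params`).
#' @param fits [fit_dataset()] output.
#' @param grid [grid_spec()] used for fitting (for the step units).
#' @param model which model's fits to evaluate.
#' @return data frame with one row per parameter: `parameter`, `n`, `bias`,
#'   `medae`, `medae_steps`, `r`.
#' @export
recovery_report <- function(true_params, fits, grid = grid_spec(),
                            model = "M_a2bk") {
  if (is.null(true_params)) stop("no ground truth available", call. = FALSE)
  f <- fits[fits$model == model, , drop = FALSE]
  if (!nrow(f)) stop("no fits for model ", model, call. = FALSE)
  pars <- intersect(c("alpha", "alpha_rew", "alpha_nonrew", "beta", "kappa"),
                    names(f)[colSums(!is.na(f)) > 0])
  agg <- stats::aggregate(f[pars],
                          by = list(subject_id = f$subject_id,
                                    phase = f$phase),
                          FUN = mean)
  truth <- true_params
  if (!"alpha" %in% names(truth) && "alpha" %in% pars)
    truth$alpha <- (truth$alpha_rew + truth$alpha_nonrew) / 2
  merged <- merge(agg, truth, by = c("subject_id", "phase"),
                  suffixes = c(".fit", ".true"))
  steps <- c(alpha = diff(grid$alpha[1:2]), alpha_rew = diff(grid$alpha[1:2]),
             alpha_nonrew = diff(grid$alpha[1:2]),
             beta = diff(grid$beta[1:2]), kappa = diff(grid$kappa[1:2]))
  rows <- lapply(pars, function(p) {
    fit <- merged[[paste0(p, ".fit")]]
    true <- merged[[paste0(p, ".true")]]
    if (is.null(true)) return(NULL)
    err <- fit - true
    r <- if (stats::sd(true) == 0 || stats::sd(fit) == 0) NA_real_
         else stats::cor(fit, true)
    data.frame(parameter = p, n = length(err), bias = mean(err),
               medae = median(abs(err)),
               medae_steps = median(abs(err)) / steps[[p]],
               r = r, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
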