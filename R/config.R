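# Pipeline configuration, YAML round-trip, and staged execution.

pipeline_defaults <- function() {
  list(
    task = list(n_games = 12L, rounds_per_game = 5L, p_good = 0.7,
                p_reversal = 0.5, amounts = c(10, 100), slot_p_win = 0.5),
    grid = list(n_q = 101L, n_v = 21L),
    behaviour = list(tau = 0.2, ct_intercept = 0.8, ct_entropy_slope = 0.4,
                     ct_round1_extra = 0.3, ct_noise_sd = 0.3),
    windows = list(baseline = c(-3000, -1000),   # pre-choice baseline
                   choice = c(-500, 0),          # choice period
                   early = c(500, 1000),         # early response period
                   late = c(1500, 2000),         # late response period
                   pre = c(-900, -300),          # pre-outcome selection
                   post = c(300, 900),           # post-outcome response
                   glm_span = c(-1000, 1500),
                   psth_span = c(-3000, 2000)),
    rate = list(window_ms = 300, step_ms = 10),
    inference = list(alpha_sel = 0.025, cluster_threshold = 0.2,
                     cluster_alpha = 0.01, n_shuffle = 1000, n_perm = 100),
    cohort = list(n_subjects = 10L, n_sessions = 31L),
    seed = 1L)
}

#' Pipeline configuration
#'
#' Assembles the full analysis configuration with the study defaults
#' embedded: the task structure, belief grid resolution, behavioural
#' simulation parameters, all analysis windows (pre-choice baseline -3000
#' to -1000 ms, choice period -500 to 0 ms, early response 500 to 1000 ms,
#' late response 1500 to 2000 ms, pre-outcome -900 to -300 ms, post-outcome
#' 300 to 900 ms), the 300 ms / 10 ms rate estimator, and the inference
#' settings (cluster threshold +/- 0.2, cluster alpha 0.01). Unknown keys
#' are rejected; windows must be well ordered and alpha levels in (0, 1).
#'
#' @param ... named overrides of top-level sections (each a named list
#'   overriding fields of that section) or of \code{seed}.
#' @return list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- pipeline_defaults()
  overrides <- list(...)
  validate_pipeline_config(merge_config(cfg, overrides))
}

merge_config <- function(cfg, overrides) {
  for (key in names(overrides)) {
    if (!key %in% names(cfg))
      stop("unknown configuration key: ", key)
    if (is.list(cfg[[key]]) && is.list(overrides[[key]])) {
      bad <- setdiff(names(overrides[[key]]), names(cfg[[key]]))
      if (length(bad))
        stop("unknown configuration key: ", key, "$", bad[1])
      cfg[[key]][names(overrides[[key]])] <- overrides[[key]]
    } else cfg[[key]] <- overrides[[key]]
  }
  cfg
}

validate_pipeline_config <- function(cfg) {
  for (w in names(cfg$windows)) {
    win <- cfg$windows[[w]]
    if (length(win) != 2 || win[2] <= win[1])
      stop("window '", w, "' is not well ordered (end must exceed start)")
  }
  for (a in c("alpha_sel", "cluster_alpha")) {
    v <- cfg$inference[[a]]
    if (v <= 0 || v >= 1) stop(a, " must lie in (0, 1)")
  }
  if (cfg$task$p_good <= 0.5 || cfg$task$p_good >= 1)
    stop("task$p_good must lie in (0.5, 1)")
  structure(cfg, class = "pipeline_config")
}

#' Load / save a pipeline configuration as YAML
#'
#' An empty or missing-key file yields the full default configuration;
#' unknown keys and malformed windows are rejected with the offending key
#' named. Save-then-load round-trips to an identical configuration.
#'
#' @param path YAML file path.
#' @return \code{load_config} returns a validated \code{pipeline_config}.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  validate_pipeline_config(merge_config(pipeline_defaults(), raw))
}

#' @rdname load_config
#' @param cfg a \code{pipeline_config}.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf))
  yaml::write_yaml(unclass(cfg), tf)
  unname(tools::md5sum(tf))
}

#' Run the simulation-and-analysis pipeline
#'
#' Executes the requested stages in dependency order against an output
#' directory: \code{"simulate"} writes a synthetic cohort (trial tables,
#' learner outputs, optional spikes), \code{"fit-learner"} refits the grid
#' observer from the trial tables alone, \code{"fit-behaviour"} runs the
#' four behavioural regressions and the descriptive choice-time tests, and
#' \code{"analyze-neural"} runs the tripartite prediction-error analysis on
#' the cohort's spike file. Every result file is stamped with the
#' configuration hash and seed; deterministic stages are bit-identical
#' across reruns.
#'
#' @param config a \code{pipeline_config}.
#' @param stages character vector of stage names.
#' @param outdir output directory.
#' @param units optional population data.frame passed to
#'   \code{\link{generate_cohort}}.
#' @return invisibly, a list of per-stage result summaries.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("simulate", "fit-behaviour"),
                         outdir, units = NULL) {
  valid <- c("simulate", "fit-learner", "fit-behaviour", "analyze-neural")
  bad <- setdiff(stages, valid)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "),
         "; valid stages: ", paste(valid, collapse = ", "))
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(config)
  results <- list(config_hash = hash)
  tcfg <- do.call(task_config, config$task)
  bpar <- do.call(behaviour_params, config$behaviour)

  manifest_path <- file.path(outdir, "manifest.json")
  if ("simulate" %in% stages) {
    results$simulate <- generate_cohort(
      outdir, n_subjects = config$cohort$n_subjects,
      n_sessions = config$cohort$n_sessions, units = units,
      params = bpar, config = tcfg, seed = config$seed)
  }
  load_cohort_tables <- function() {
    if (!file.exists(manifest_path))
      stop("missing upstream artifact: run the 'simulate' stage first")
    man <- jsonlite::read_json(manifest_path)
    sids <- setdiff(names(man$files), "spikes")
    tabs <- lapply(sids, function(sid) {
      tt <- read_trials(file.path(outdir, man$files[[sid]]$trials))
      lt <- read_learner_output(file.path(outdir, man$files[[sid]]$learner))
      cbind(tt, lt[, c("ev_left", "ev_right", "chosen_ev", "ce",
                       "pe_binary", "pe_amount")])
    })
    names(tabs) <- sids
    tabs
  }
  if ("fit-learner" %in% stages) {
    tabs <- load_cohort_tables()
    refits <- lapply(names(tabs), function(sid) {
      fit <- reversal_learner(read_trials(
        file.path(outdir, paste0(sid, "_trials.csv"))),
        n_q = config$grid$n_q, n_v = config$grid$n_v)
      write_learner_output(fit, file.path(outdir, paste0(sid, "_learner.csv")))
      sid
    })
    results$fit_learner <- unlist(refits)
  }
  if ("fit-behaviour" %in% stages) {
    tabs <- load_cohort_tables()
    data <- do.call(rbind, tabs)
    fits <- list(choice = fit_choice_model(data),
                 choice_time = fit_choice_time_model(data),
                 lagged_outcome = lagged_outcome_regression(data),
                 lagged_pe = lagged_pe_regression(data))
    for (nm in names(fits))
      write_regression_result(fits[[nm]],
                              file.path(outdir, paste0(nm, "_coefs.csv")),
                              file.path(outdir, paste0(nm, "_group.json")))
    rt <- rt_descriptive_tests(data)
    jsonlite::write_json(list(config_hash = hash, seed = config$seed,
                              tests = rt, log = attr(rt, "log")),
                         file.path(outdir, "rt_tests.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    results$fit_behaviour <- fits
  }
  if ("analyze-neural" %in% stages) {
    tabs <- load_cohort_tables()
    spike_file <- file.path(outdir, "spikes.csv")
    if (!file.exists(spike_file))
      stop("missing upstream artifact: no spikes.csv; run 'simulate' with units")
    trains <- read_spikes(spike_file)
    cohort <- sliding_glm_cohort(trains, tabs,
                                 span = config$windows$psth_span,
                                 glm_span = config$windows$glm_span,
                                 n_perm = config$inference$n_perm,
                                 seed = config$seed)
    areas <- unique(vapply(cohort, `[[`, "", "area"))
    neural <- lapply(areas, function(a)
      tripartite_pe_test(cohort, a,
                         choice_window = config$windows$pre,
                         response_window = config$windows$post,
                         alpha_sel = config$inference$alpha_sel,
                         n_shuffle = config$inference$n_shuffle,
                         threshold = config$inference$cluster_threshold,
                         alpha_cluster = config$inference$cluster_alpha,
                         seed = config$seed))
    names(neural) <- areas
    jsonlite::write_json(
      list(config_hash = hash, seed = config$seed,
           results = lapply(neural, function(x)
             list(area = x$area, n_selected = x$n_selected,
                  amount_positive = x$amount_positive,
                  ev_negative = x$ev_negative,
                  pe_positive = x$pe_positive))),
      file.path(outdir, "neural_pe.json"), auto_unbox = TRUE, digits = NA)
    results$analyze_neural <- neural
  }
  invisible(results)
}
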