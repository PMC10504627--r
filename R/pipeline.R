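# End-to-end orchestration: simulate (or load) raw streams, preprocess,
# profile, run change-point detection, alarm, evaluate. One master seed
# derives every stage seed; all intermediate artifacts are written under an
# output directory together with a run manifest.

#' Pipeline configuration
#'
#' @param scenario a [scenario_config()] for the synthetic cohort (ignored
#'   when `stream_paths` is given).
#' @param stream_paths optional character vector of JSONL raw-stream paths to
#'   analyse instead of simulating.
#' @param night_window,home_radius_m preprocessing parameters.
#' @param K_max,n_restarts,tol profiling parameters.
#' @param hazard,alpha,n_samples,run_length_cap change-point parameters, see
#'   [bocpd_config()].
#' @param tau stability threshold used for the alarm CSVs.
#' @param horizon,n_thresholds,burn_in evaluation parameters.
#' @param seed master seed; stage seeds are derived from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(scenario = scenario_config(),
                            stream_paths = NULL,
                            night_window = c(0, 6), home_radius_m = 200,
                            K_max = 5, n_restarts = 3, tol = 1e-5,
                            hazard = 1 / 60, alpha = 1, n_samples = 0,
                            run_length_cap = 365,
                            tau = 0.5, horizon = 7, n_thresholds = 50,
                            burn_in = 7, seed = 1) {
  if (tau <= 0 || tau >= 1) stop_invalid("tau must lie in (0, 1)")
  structure(list(scenario = scenario, stream_paths = stream_paths,
                 night_window = night_window, home_radius_m = home_radius_m,
                 K_max = K_max, n_restarts = n_restarts, tol = tol,
                 hazard = hazard, alpha = alpha, n_samples = n_samples,
                 run_length_cap = run_length_cap, tau = tau,
                 horizon = horizon, n_thresholds = n_thresholds,
                 burn_in = burn_in, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_msg <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                               sprintf(fmt, ...)))
}

#' Run the full monitoring pipeline
#'
#' Simulate (or load) raw sensor streams, build daily features, fit the
#' per-patient profile mixture with BIC selection, run the change-point
#' detector, raise stability-threshold alarms, and — when risk events are
#' available — compute the pooled day-level ROC. Writes features, models,
#' posteriors, alarms, ROC and a manifest under `out_dir`.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed); `NULL` writes
#'   nothing.
#' @param verbose print per-stage progress.
#' @return list with per-patient `features`, `profiling`, `run_length`,
#'   `change_prob`, `alarms`, plus `events`, `summary`, `roc` (NULL if the
#'   cohort is degenerate) and `manifest`.
#' @export
run_pipeline <- function(config, out_dir = NULL, verbose = FALSE) {
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  t0 <- Sys.time()
  # --- stage: collect -------------------------------------------------
  if (is.null(config$stream_paths)) {
    stage_msg(verbose, "simulating %d patients", config$scenario$n_patients)
    cohort <- tryCatch(generate_cohort(config$scenario),
                       error = function(e) stop("simulate stage: ",
                                                conditionMessage(e),
                                                call. = FALSE))
    streams <- lapply(cohort, `[[`, "stream")
    truths <- lapply(cohort, `[[`, "truth")
    n_days_each <- rep(config$scenario$days_per_patient, length(streams))
  } else {
    missing_paths <- config$stream_paths[!file.exists(config$stream_paths)]
    if (length(missing_paths))
      stop("collect stage: input path not found: ",
           paste(missing_paths, collapse = ", "), call. = FALSE)
    streams <- lapply(config$stream_paths, read_stream_jsonl)
    truths <- NULL
    n_days_each <- rep(list(NULL), length(streams))
  }
  n <- length(streams)
  # --- stage: preprocess ----------------------------------------------
  stage_msg(verbose, "preprocessing %d streams", n)
  features <- lapply(seq_len(n), function(i)
    tryCatch(build_daily_features(streams[[i]], config$night_window,
                                  config$home_radius_m,
                                  n_days = n_days_each[[i]]),
             error = function(e) stop("preprocess stage (patient ", i, "): ",
                                      conditionMessage(e), call. = FALSE)))
  # --- stage: profile -------------------------------------------------
  stage_msg(verbose, "profiling (K_max = %d)", config$K_max)
  profiling <- lapply(seq_len(n), function(i)
    tryCatch(select_profiles(features[[i]], K_max = config$K_max,
                             n_restarts = config$n_restarts,
                             tol = config$tol,
                             seed = derive_seed(config$seed, i)),
             error = function(e) stop("profile stage (patient ", i, "): ",
                                      conditionMessage(e), call. = FALSE)))
  # --- stage: changepoint ----------------------------------------------
  stage_msg(verbose, "change-point detection")
  run_length <- lapply(seq_len(n), function(i) {
    cfg <- bocpd_config(hazard = config$hazard, alpha = config$alpha,
                        n_samples = config$n_samples,
                        seed = derive_seed(config$seed, 10000 + i),
                        run_length_cap = config$run_length_cap)
    run_bocpd(profiling[[i]]$posterior, cfg)
  })
  change_prob <- lapply(run_length, change_window_probability,
                        w = config$burn_in)
  # --- stage: detect ---------------------------------------------------
  alarms <- lapply(change_prob, detect_alarms, tau = config$tau,
                   burn_in = config$burn_in)
  # --- stage: evaluate -------------------------------------------------
  events <- if (!is.null(truths)) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      ev <- truths[[i]]$events
      if (nrow(ev) == 0) return(NULL)
      cbind(patient_id = streams[[i]]$patient_id, ev[1, , drop = FALSE])
    }))
  } else NULL
  roc <- NULL
  summary <- NULL
  if (!is.null(truths)) {
    event_days <- vapply(truths, function(tr)
      if (nrow(tr$events)) as.numeric(tr$events$day[1]) else NA_real_,
      numeric(1))
    summary <- cohort_summary(
      if (is.null(events)) data.frame(patient_id = character(),
                                      day = integer(), type = character())
      else events, n)
    roc <- tryCatch(
      roc_curve(change_prob, event_days, n_thresholds = config$n_thresholds,
                horizon = config$horizon, burn_in = config$burn_in),
      error = function(e) { stage_msg(verbose, "evaluate stage skipped: %s",
                                      conditionMessage(e)); NULL })
  }
  manifest <- list(
    seed = config$seed, n_patients = n,
    config_hash = digest_config(config),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
    selected_K = vapply(profiling, `[[`, numeric(1), "K"))
  # --- write artifacts -------------------------------------------------
  if (!is.null(out_dir)) {
    for (i in seq_len(n)) {
      pid <- streams[[i]]$patient_id
      write_features_csv(features[[i]],
                         file.path(out_dir, paste0(pid, "_features.csv")))
      write_model_json(profiling[[i]]$model,
                       file.path(out_dir, paste0(pid, "_model.json")))
      write_posterior_csv(profiling[[i]]$posterior,
                          file.path(out_dir, paste0(pid, "_posterior.csv")))
      write_runlength_csv(run_length[[i]],
                          file.path(out_dir, paste0(pid, "_runlength.csv")))
      write_alarms_csv(alarms[[i]], pid,
                       file.path(out_dir, paste0(pid, "_alarms.csv")))
    }
    if (!is.null(events))
      utils::write.csv(events, file.path(out_dir, "events.csv"),
                       row.names = FALSE)
    if (!is.null(roc))
      write_roc(roc, file.path(out_dir, "roc.csv"),
                file.path(out_dir, "roc.json"))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(features = features, profiling = profiling, run_length = run_length,
       change_prob = change_prob, alarms = alarms, events = events,
       summary = summary, roc = roc, manifest = manifest)
}

# Stable hash-like fingerprint of a config (no external digest dependency).
digest_config <- function(config) {
  s <- jsonlite::toJSON(config[setdiff(names(config), "stream_paths")],
                        auto_unbox = TRUE, digits = 12, force = TRUE)
  sum(utf8ToInt(as.character(s)) * seq_len(nchar(as.character(s)))) %%
    2147483647
}

#' Read a pipeline configuration from JSON
#'
#' The JSON mirrors the arguments of [pipeline_config()] and
#' [scenario_config()] (`scenario` as a nested object; `profiles` as a list
#' of [profile_params()] argument lists).
#'
#' @param path JSON config path.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  scen <- scenario_config()
  if (!is.null(js$scenario)) {
    args <- js$scenario
    if (!is.null(args$profiles)) {
      if (is.data.frame(args$profiles))    # simplifyVector tabularizes them
        args$profiles <- lapply(seq_len(nrow(args$profiles)), function(i)
          as.list(args$profiles[i, ]))
      args$profiles <- lapply(args$profiles, function(p)
        do.call(profile_params, as.list(p)))
    }
    if (!is.null(args$segments) && is.data.frame(args$segments))
      args$segments <- lapply(seq_len(nrow(args$segments)), function(i)
        list(start_day = args$segments$start_day[i],
             profile_dist = args$segments$profile_dist[[i]]))
    scen <- do.call(scenario_config, args)
  }
  rest <- js[setdiff(names(js), "scenario")]
  do.call(pipeline_config, c(list(scenario = scen), rest))
}
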