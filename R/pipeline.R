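# Pipeline orchestration: simulate (or load) -> QC -> mirror-normalise ->
# inclusion -> kernel extraction & parameterisation -> LN validation ->
# group statistics, with CSV/JSON outputs and a reproducibility manifest.

# Default comparison panels mirroring the figure families: impulse size,
# constant roll, constant lift.
.default_panels <- function(labels) {
  panels <- list(
    impulse_size = c("roll18", "roll33", "roll48"),
    constant_roll = c("roll33_ir50", "roll33_ir25", "roll33",
                      "roll33_er25", "roll33_er50"),
    constant_lift = c("roll33_lift-50", "roll33", "roll33_lift+50")
  )
  panels <- lapply(panels, intersect, labels)
  panels[lengths(panels) >= 2]
}

# Neuron-relative (mirror-normalised) copy of a dataset's traces.
.normalize_dataset <- function(dataset) {
  sides <- vapply(dataset$neurons, function(n) n$model$side, character(1))
  names(sides) <- vapply(dataset$neurons, function(n) n$neuron_id,
                         character(1))
  dataset$trials <- lapply(dataset$trials, function(t) {
    t$trace <- mirror_normalize(t$trace, sides[[t$neuron_id]])
    t
  })
  dataset
}

#' Run the full analysis pipeline
#'
#' Stages: (1) simulate a synthetic dataset from `config` (or take
#' `dataset` as given); (2) QC every trial on its frame log; (3)
#' mirror-normalise traces by receptive-field side; (4) apply the inclusion
#' criteria (preferred-roll gate, 5 Hz condition gate); (5) estimate the
#' impulse response and the six kernel parameters per retained
#' neuron-condition; (6) LN validation on the shared trial (leave-one-out
#' correlations and the shuffled-spike control); (7) nonparametric group
#' statistics over the parameter table. Writes CSV/JSON results plus a
#' manifest when `out_dir` is given; reruns with the same config are
#' deterministic.
#'
#' @param config Configuration from [default_config()].
#' @param out_dir Output directory (created if missing); `NULL` to skip
#'   writing.
#' @param dataset Optional pre-built dataset (e.g. from
#'   [load_recordings()]); when supplied, `config` defaults to the
#'   dataset's own.
#' @param validate Run the LN validation stage (default `TRUE`).
#' @param n_shuffles Shuffles per neuron for the control (default 20).
#' @return List with `param_table`, `kernels` (per neuron-condition
#'   `impulse_response`), `inclusion`, `validation`, `shuffle`, `stats`,
#'   `qc_report`, `manifest`.
#' @export
run_pipeline <- function(config = default_config(), out_dir = NULL,
                         dataset = NULL, validate = TRUE, n_shuffles = 20) {
  if (is.null(dataset)) {
    dataset <- simulate_experiment(config)
  } else if (!is.null(dataset$config)) {
    config <- dataset$config
  }
  log_lines <- character()
  say <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  # --- QC ------------------------------------------------------------
  dataset$trials <- lapply(dataset$trials, qc_trial)
  qc_report <- do.call(rbind, lapply(dataset$trials, function(t) {
    data.frame(neuron_id = t$neuron_id, condition = t$condition,
               trial = t$trial, keep = t$keep, reason = t$reason,
               stringsAsFactors = FALSE)
  }))
  say("QC: %d/%d trials kept", sum(qc_report$keep), nrow(qc_report))
  kept <- dataset
  kept$trials <- dataset$trials[vapply(dataset$trials, `[[`, logical(1),
                                       "keep")]

  # --- mirror normalisation -----------------------------------------
  kept <- .normalize_dataset(kept)

  # --- inclusion -----------------------------------------------------
  cond_rates <- do.call(rbind, lapply(split(
    kept$trials, paste(vapply(kept$trials, `[[`, character(1), "neuron_id"),
                       vapply(kept$trials, `[[`, character(1), "condition"),
                       sep = "\r")), function(trs) {
    data.frame(neuron_id = trs[[1]]$neuron_id,
               condition = trs[[1]]$condition,
               rate_hz = mean(vapply(trs, function(t)
                 spike_rate_analysed(t$trace, t$train), numeric(1))),
               stringsAsFactors = FALSE)
  }))
  rownames(cond_rates) <- NULL
  inclusion <- apply_inclusion(kept$preferred_roll_rate_hz, cond_rates)
  say("inclusion: %d/%d neurons kept, %d neuron-conditions excluded",
      length(inclusion$neurons_kept), length(kept$preferred_roll_rate_hz),
      sum(!is.na(inclusion$report$condition)))

  # --- kernels and parameters ---------------------------------------
  kernels <- list()
  param_table <- NULL
  for (i in seq_len(nrow(inclusion$conditions_kept))) {
    nid <- inclusion$conditions_kept$neuron_id[i]
    cond <- inclusion$conditions_kept$condition[i]
    trs <- dataset_trials(kept, neuron_id = nid, condition = cond)
    res <- tryCatch({
      ir <- estimate_kernel(trs)
      params <- extract_params(ir)
      kernels[[paste(nid, cond, sep = ":")]] <- ir
      params_row(params, nid, cond)
    }, error = function(e) {
      say("kernel failed for %s/%s: %s", nid, cond, conditionMessage(e))
      NULL
    })
    param_table <- rbind(param_table, res)
  }
  say("kernels: %d neuron-conditions parameterised", nrow(param_table))

  # --- LN validation -------------------------------------------------
  validation <- shuffle <- NULL
  if (validate) {
    validation <- tryCatch(loo_correlations(kept), error = function(e) {
      say("validation skipped: %s", conditionMessage(e))
      NULL
    })
    shuffle <- tryCatch(shuffle_control(kept, n_shuffles = n_shuffles),
                        error = function(e) {
      say("shuffle control skipped: %s", conditionMessage(e))
      NULL
    })
  }

  # --- group statistics ----------------------------------------------
  stats_res <- NULL
  if (!is.null(param_table) && length(unique(param_table$condition)) >= 2) {
    panels <- .default_panels(unique(param_table$condition))
    if (length(panels) == 0)
      panels <- list(all = unique(param_table$condition))
    stats_res <- param_stats(param_table, panels)
  }

  manifest <- list(
    package = "rollkernel",
    version = tryCatch(as.character(utils::packageVersion("rollkernel")),
                       error = function(e) NA_character_),
    seed = config$seed,
    n_neurons = config$n_neurons,
    n_trials = config$n_trials,
    conditions = vapply(config$conditions, function(cc) cc$label,
                        character(1)),
    shared_condition = config$shared_condition,
    shared_trial = config$shared_trial,
    drop_prob = config$drop_prob,
    neuron = config$neuron,
    log = log_lines
  )
  results <- list(param_table = param_table, kernels = kernels,
                  inclusion = inclusion, validation = validation,
                  shuffle = shuffle, stats = stats_res,
                  qc_report = qc_report, manifest = manifest)
  if (!is.null(out_dir)) write_results(results, out_dir)
  results
}

#' Write pipeline results to a directory
#'
#' @param results Output of [run_pipeline()].
#' @param out_dir Target directory (created recursively).
#' @return `out_dir`, invisibly.
#' @export
write_results <- function(results, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(results$param_table,
                   file.path(out_dir, "kernel_parameters.csv"),
                   row.names = FALSE)
  utils::write.csv(results$qc_report, file.path(out_dir, "qc_report.csv"),
                   row.names = FALSE)
  utils::write.csv(results$inclusion$report,
                   file.path(out_dir, "inclusion_report.csv"),
                   row.names = FALSE)
  if (!is.null(results$stats)) {
    utils::write.csv(results$stats$omnibus,
                     file.path(out_dir, "stats_omnibus.csv"),
                     row.names = FALSE)
    utils::write.csv(results$stats$pairwise,
                     file.path(out_dir, "stats_pairwise.csv"),
                     row.names = FALSE)
  }
  kern_df <- do.call(rbind, lapply(names(results$kernels), function(key) {
    ir <- results$kernels[[key]]
    parts <- strsplit(key, ":", fixed = TRUE)[[1]]
    data.frame(neuron_id = parts[1], condition = parts[2],
               lag_ms = ir$lags, value = ir$values, stringsAsFactors = FALSE)
  }))
  if (!is.null(kern_df))
    utils::write.csv(kern_df, file.path(out_dir, "kernels.csv"),
                     row.names = FALSE)
  val <- list(
    loo = if (!is.null(results$validation)) list(
      per_neuron = as.list(results$validation$per_neuron),
      median_r = results$validation$median_r,
      range_r = results$validation$range_r) else NULL,
    shuffle = if (!is.null(results$shuffle)) list(
      per_neuron_mean = as.list(results$shuffle$per_neuron_mean),
      median_r = results$shuffle$median_r,
      range_r = results$shuffle$range_r,
      n_shuffles = results$shuffle$n_shuffles) else NULL
  )
  jsonlite::write_json(val, file.path(out_dir, "validation.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  jsonlite::write_json(results$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Export a dataset as CSV trials plus a JSON manifest
#'
#' One spike CSV (`spike_time_s`) and one trace CSV per trial, listed in
#' `manifest.json` together with neuron metadata (side, preferred-roll
#' rate) and condition definitions, so that [load_recordings()] can rebuild
#' an equivalent dataset.
#'
#' @param dataset A `synthetic_dataset`.
#' @param dir Target directory.
#' @return `dir`, invisibly.
#' @export
export_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trials_meta <- list()
  for (i in seq_along(dataset$trials)) {
    t <- dataset$trials[[i]]
    base <- sprintf("%s_%s_t%02d", t$neuron_id, t$condition, t$trial)
    spike_file <- paste0(base, "_spikes.csv")
    trace_file <- paste0(base, "_trace.csv")
    utils::write.csv(data.frame(spike_time_s = t$train$times),
                     file.path(dir, spike_file), row.names = FALSE)
    write_trace_csv(t$trace, file.path(dir, trace_file))
    trials_meta[[i]] <- list(
      neuron_id = t$neuron_id, condition = t$condition, trial = t$trial,
      shared = isTRUE(t$shared), duration_s = t$train$duration,
      spikes = spike_file, trace = trace_file,
      base_impulse_deg = t$trace$condition$base_impulse_deg,
      constant_roll_dps = t$trace$condition$constant_roll_dps,
      constant_lift_cmps = t$trace$condition$constant_lift_cmps,
      frame_rate_hz = t$trace$frame_rate_hz,
      analysis_length = t$trace$analysis_length
    )
  }
  neurons_meta <- lapply(dataset$neurons, function(n) list(
    neuron_id = n$neuron_id, side = n$model$side,
    preferred_roll_rate_hz =
      unname(dataset$preferred_roll_rate_hz[n$neuron_id])
  ))
  jsonlite::write_json(list(
    seed = dataset$config$seed,
    shared_condition = dataset$config$shared_condition,
    shared_trial = dataset$config$shared_trial,
    neurons = neurons_meta,
    trials = trials_meta
  ), file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a recorded or exported dataset from a directory
#'
#' Reads the `manifest.json` schema written by [export_dataset()]. Trials
#' with missing or malformed files are dropped with a logged reason; an
#' empty or manifest-less directory is an error.
#'
#' @param dir Directory containing `manifest.json` and the trial CSVs.
#' @return A dataset structurally equivalent to [simulate_experiment()]
#'   output (class `synthetic_dataset`), with a `load_log` field listing
#'   dropped trials.
#' @export
load_recordings <- function(dir) {
  mf_path <- file.path(dir, "manifest.json")
  if (!file.exists(mf_path))
    stop(sprintf("no trials found: %s is missing", mf_path), call. = FALSE)
  mf <- jsonlite::read_json(mf_path, simplifyVector = FALSE)
  if (length(mf$trials) == 0)
    stop("no trials found in manifest", call. = FALSE)
  load_log <- character()
  neurons <- lapply(mf$neurons, function(n) list(
    neuron_id = n$neuron_id,
    model = ln_model(side = n$side)  # placeholder model: side + id metadata
  ))
  pref <- vapply(mf$neurons, function(n)
    as.numeric(n$preferred_roll_rate_hz %||% NA_real_), numeric(1))
  names(pref) <- vapply(mf$neurons, function(n) n$neuron_id, character(1))
  trials <- list()
  for (tm in mf$trials) {
    res <- tryCatch({
      spikes <- utils::read.csv(file.path(dir, tm$spikes))
      if (!"spike_time_s" %in% names(spikes))
        stop(sprintf("%s: missing column spike_time_s", tm$spikes),
             call. = FALSE)
      cond <- flow_condition(tm$base_impulse_deg, tm$constant_roll_dps,
                             tm$constant_lift_cmps, label = tm$condition)
      trace <- read_trace_csv(file.path(dir, tm$trace), cond,
                              frame_rate_hz = tm$frame_rate_hz,
                              analysis_length = tm$analysis_length)
      train <- spike_train(spikes$spike_time_s, duration = tm$duration_s,
                           neuron_id = tm$neuron_id,
                           condition = tm$condition, trial = tm$trial)
      list(neuron_id = tm$neuron_id, condition = tm$condition,
           trial = tm$trial, shared = isTRUE(tm$shared),
           trace = trace, train = train, mseq = NULL)
    }, error = function(e) {
      load_log <<- c(load_log, sprintf("%s/%s trial %s dropped: %s",
                                       tm$neuron_id, tm$condition, tm$trial,
                                       conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) trials[[length(trials) + 1L]] <- res
  }
  if (length(trials) == 0)
    stop("no trials found: every trial failed to load", call. = FALSE)
  labels <- unique(vapply(trials, `[[`, character(1), "condition"))
  conditions <- lapply(labels, function(lb) {
    t <- trials[[which(vapply(trials, `[[`, character(1),
                              "condition") == lb)[1]]]
    t$trace$condition
  })
  config <- list(
    n_neurons = length(neurons),
    n_trials = max(vapply(trials, function(t) as.integer(t$trial),
                          integer(1))),
    order = 8L, extended_length = 400L,
    shared_condition = mf$shared_condition %||% "roll33",
    shared_trial = as.integer(mf$shared_trial %||% 2L),
    drop_prob = 0, seed = as.numeric(mf$seed %||% NA_real_),
    conditions = conditions,
    neuron = list(), screen = screen_geometry()
  )
  structure(list(neurons = neurons, trials = trials,
                 preferred_roll_rate_hz = pref,
                 condition_labels = labels,
                 config = config, load_log = load_log),
            class = "synthetic_dataset")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
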