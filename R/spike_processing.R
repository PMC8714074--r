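# Spike-train representation, windowed rates, trial QC, inclusion rules and
# receptive-field side normalisation.

#' Construct a spike train
#'
#' @param times Spike times (s), sorted ascending, within `[0, duration)`.
#' @param duration Trial duration (s).
#' @param neuron_id,condition,trial Optional identifiers.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(times, duration, neuron_id = NA, condition = NA,
                        trial = NA) {
  times <- as.numeric(times)
  if (is.unsorted(times)) times <- sort(times)
  if (length(times) > 0 && (times[1] < 0 || times[length(times)] >= duration))
    stop("spike times must lie in [0, duration)", call. = FALSE)
  structure(list(
    times = times, duration = duration,
    neuron_id = neuron_id, condition = condition, trial = trial
  ), class = "spike_train")
}

#' Bin spikes into counts
#'
#' Floor convention: a spike at time t falls in bin `floor(t / resolution)`,
#' so a spike at 10.4 ms with 1 ms bins lands in the bin covering
#' `[10, 11)` ms.
#'
#' @param train A `spike_train`.
#' @param resolution_ms Bin width (ms, default 1).
#' @param n_bins Number of bins; defaults to
#'   `ceiling(duration / resolution)`.
#' @return Integer count vector summing to the number of spikes.
#' @export
bin_spikes <- function(train, resolution_ms = 1, n_bins = NULL) {
  stopifnot(resolution_ms > 0)
  res_s <- resolution_ms / 1000
  if (is.null(n_bins)) n_bins <- ceiling(train$duration / res_s)
  idx <- floor(train$times / res_s) + 1L
  idx <- idx[idx >= 1L & idx <= n_bins]
  counts <- integer(n_bins)
  if (length(idx) > 0) {
    tab <- tabulate(idx, nbins = n_bins)
    counts <- tab
  }
  counts
}

#' Mean firing rate in a window
#'
#' Spike count in `[t0, t1)` divided by the window length. The study's
#' response window for continuous-motion trials drops the first 100 ms after
#' onset; the spontaneous window is the 0.5 s immediately preceding onset.
#'
#' @param train A `spike_train`.
#' @param t0,t1 Window bounds (s), `t1 > t0`, within the trial.
#' @return Rate in Hz.
#' @export
mean_rate <- function(train, t0 = 0, t1 = train$duration) {
  if (t1 <= t0) stop("t1 must be > t0", call. = FALSE)
  if (t0 < 0 || t1 > train$duration + 1e-9)
    stop("window outside the trial", call. = FALSE)
  sum(train$times >= t0 & train$times < t1) / (t1 - t0)
}

#' Quality-control a trial on its frame log
#'
#' A trial with any dropped frame is discarded in full (the photodiode rule
#' used during acquisition); a trial without a frame log is discarded with a
#' distinct reason.
#'
#' @param trial A list with fields `trace` (a `stimulus_trace`) and `train`
#'   (a `spike_train`).
#' @return The trial with logical `keep` and character `reason` fields added
#'   (class `trial_record`).
#' @export
qc_trial <- function(trial) {
  log <- trial$trace$presented
  if (is.null(log)) {
    trial$keep <- FALSE
    trial$reason <- "no_frame_log"
  } else if (!all(log)) {
    trial$keep <- FALSE
    trial$reason <- "dropped_frames"
  } else {
    trial$keep <- TRUE
    trial$reason <- ""
  }
  class(trial) <- "trial_record"
  trial
}

#' Inclusion thresholds
#'
#' The neuron-level gate is 80% of the previously reported mean
#' preferred-direction roll response (199 spikes/s), i.e. 159 spikes/s after
#' rounding; neurons strictly below it are excluded. The condition-level
#' gate removes neuron-conditions whose mean rate over trials is below
#' 5 spikes/s.
#'
#' @param reported_mean_hz Published mean preferred-roll response (Hz).
#' @param fraction Fraction of the reported mean used as the gate.
#' @return The neuron-level threshold in Hz (`round(fraction * reported)`).
#' @export
inclusion_threshold <- function(reported_mean_hz = 199, fraction = 0.8) {
  round(fraction * reported_mean_hz)
}

#' Apply the protocol's inclusion criteria
#'
#' Removes whole neurons whose preferred-direction roll rate is strictly
#' below the neuron gate (default `round(0.8 * 199) = 159` Hz; exactly 159
#' is kept), then removes neuron-conditions whose mean rate over trials is
#' strictly below `min_condition_rate_hz`.
#'
#' @param preferred_roll_rates Named numeric vector: mean preferred-roll
#'   rate (Hz) per neuron.
#' @param condition_rates Data frame with columns `neuron_id`, `condition`,
#'   `rate_hz`: mean rate over trials per neuron-condition.
#' @param neuron_threshold_hz Neuron-level gate (Hz).
#' @param min_condition_rate_hz Condition-level gate (Hz, default 5).
#' @return A list with `neurons_kept`, `conditions_kept` (data frame of
#'   retained neuron-conditions) and `report` (data frame `neuron_id`,
#'   `condition`, `reason` with one row per exclusion; `condition` is `NA`
#'   for whole-neuron exclusions).
#' @export
apply_inclusion <- function(preferred_roll_rates, condition_rates,
                            neuron_threshold_hz = inclusion_threshold(),
                            min_condition_rate_hz = 5) {
  neurons <- names(preferred_roll_rates)
  if (is.null(neurons))
    stop("'preferred_roll_rates' must be named by neuron", call. = FALSE)
  low <- preferred_roll_rates < neuron_threshold_hz
  report <- data.frame(neuron_id = character(), condition = character(),
                       reason = character(), stringsAsFactors = FALSE)
  if (any(low)) {
    report <- rbind(report, data.frame(
      neuron_id = neurons[low], condition = NA_character_,
      reason = sprintf("preferred_roll_rate_below_%g_hz", neuron_threshold_hz),
      stringsAsFactors = FALSE))
  }
  neurons_kept <- neurons[!low]
  cr <- condition_rates[condition_rates$neuron_id %in% neurons_kept, ,
                        drop = FALSE]
  low_cond <- cr$rate_hz < min_condition_rate_hz
  if (any(low_cond)) {
    report <- rbind(report, data.frame(
      neuron_id = cr$neuron_id[low_cond], condition = cr$condition[low_cond],
      reason = sprintf("condition_rate_below_%g_hz", min_condition_rate_hz),
      stringsAsFactors = FALSE))
  }
  list(
    neurons_kept = neurons_kept,
    conditions_kept = cr[!low_cond, c("neuron_id", "condition"), drop = FALSE],
    report = report
  )
}

#' Mirror-normalise a stimulus trace for receptive-field side
#'
#' Responses of right-side neurons are mirror images of left-side ones; so
#' that "excitatory roll" is positive for every neuron, traces recorded for
#' right-side neurons have their sign sequence and roll increments negated.
#' Lift is unchanged (downward lift excites both sides). Applying the
#' normalisation twice returns the original trace.
#'
#' @param trace A `stimulus_trace`.
#' @param side `"left"` or `"right"`.
#' @return The (possibly mirrored) `stimulus_trace`.
#' @export
mirror_normalize <- function(trace, side) {
  if (!side %in% c("left", "right"))
    stop(sprintf("unknown receptive-field side '%s'", side), call. = FALSE)
  if (side == "right") {
    trace$sign_sequence <- -trace$sign_sequence
    trace$roll_increment_deg <- -trace$roll_increment_deg
  }
  trace
}
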