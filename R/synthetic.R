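# Ground-truth linear-nonlinear (LN) spiking neurons driven by the stimulus
# protocol. The generator exists so that every downstream stage (QC,
# inclusion, kernel extraction, LN validation, statistics) can be exercised
# end to end against known ground truth, with no recorded data.

#' Build a parametric causal kernel
#'
#' Log-normal-in-lag shape with exact peak placement: the peak value equals
#' `amplitude` at lag `ttp_ms` and the full width at half maximum equals
#' `half_width_ms` (closed form:
#' `sigma = asinh(half_width / (2 ttp)) / sqrt(2 log 2)`). An optional slow
#' positive tail can be added to probe return-to-baseline behaviour; it is
#' off by default.
#'
#' @param amplitude Peak value (arbitrary drive units).
#' @param ttp_ms Time to peak (ms), `0 < ttp < length_ms`.
#' @param half_width_ms Full width at half maximum (ms, > 0).
#' @param length_ms Kernel support length (ms, default 300).
#' @param tail_amplitude Amplitude of an optional slow exponential tail
#'   starting at the peak (default 0, i.e. no tail).
#' @param tail_tau_ms Time constant of the optional tail (ms).
#' @return Numeric vector of kernel values on the 1 ms lag grid
#'   `0 .. length_ms` (index 1 = lag 0, which is always 0).
#' @export
make_kernel <- function(amplitude = 1, ttp_ms = 18, half_width_ms = 12,
                        length_ms = 300, tail_amplitude = 0,
                        tail_tau_ms = 150) {
  if (!(ttp_ms > 0 && ttp_ms < length_ms))
    stop("'ttp_ms' must satisfy 0 < ttp < length_ms", call. = FALSE)
  if (half_width_ms <= 0) stop("'half_width_ms' must be > 0", call. = FALSE)
  lags <- 0:length_ms
  sigma <- asinh(half_width_ms / (2 * ttp_ms)) / sqrt(2 * log(2))
  h <- numeric(length(lags))
  pos <- lags > 0
  h[pos] <- amplitude * exp(-(log(lags[pos] / ttp_ms))^2 / (2 * sigma^2))
  if (tail_amplitude != 0) {
    after <- lags > ttp_ms
    h[after] <- h[after] +
      tail_amplitude * exp(-(lags[after] - ttp_ms) / tail_tau_ms)
  }
  h
}

#' Define a ground-truth LN neuron
#'
#' The neuron's drive is the stimulus increments convolved with a causal
#' kernel: roll increments (degrees per frame, including any constant-flow
#' component) are scaled by `roll_gain` (drive per degree) and lift
#' increments (cm per frame) by `lift_gain` (drive per cm, positive for
#' excitatory, i.e. downward, lift). Firing rate is a rectified-linear
#' function of drive saturating at `rmax_hz`.
#'
#' @param kernel Causal kernel on the 1 ms grid (see [make_kernel()]).
#' @param roll_gain Drive units per degree of roll increment.
#' @param lift_gain Drive units per cm of lift increment.
#' @param r0_hz Baseline (spontaneous) rate, Hz.
#' @param slope_hz Slope of the output nonlinearity (Hz per drive unit).
#' @param rmax_hz Saturation rate, Hz.
#' @param side Receptive-field side, `"left"` or `"right"`; right-side
#'   neurons receive sign-flipped roll drive.
#' @return An object of class `ln_model`.
#' @export
ln_model <- function(kernel = make_kernel(), roll_gain = 260, lift_gain = 60,
                     r0_hz = 30, slope_hz = 1, rmax_hz = 300,
                     side = "left") {
  stopifnot(r0_hz >= 0, rmax_hz > r0_hz, slope_hz > 0,
            side %in% c("left", "right"))
  structure(list(
    kernel = kernel, roll_gain = roll_gain, lift_gain = lift_gain,
    r0_hz = r0_hz, slope_hz = slope_hz, rmax_hz = rmax_hz, side = side
  ), class = "ln_model")
}

# Millisecond sample indices of frame onsets. The epsilon guards against
# frame times that are an exact multiple of 1 ms up to floating-point error.
.onset_idx <- function(trace) floor(trace$frame_times_s * 1000 + 1e-6) + 1L

# Causal convolution of an impulse series (1 ms grid) with a kernel whose
# first element is lag 0.
.conv_causal <- function(x, kernel) {
  n <- length(x)
  out <- stats::convolve(c(x, numeric(length(kernel))), rev(kernel),
                         type = "open")
  out[seq_len(n)]
}

#' LN firing rate for a stimulus trace
#'
#' Places each frame's roll and lift increments as impulses at the frame
#' onset sample on a 1 ms grid, convolves with the neuron's kernel, and maps
#' the summed drive through the rectified saturating nonlinearity
#' `r(t) = min(rmax, max(0, r0 + slope * u(t)))`. Dropped frames contribute
#' no drive. Right-side neurons get sign-flipped roll drive.
#'
#' @param trace A `stimulus_trace`.
#' @param model An `ln_model`.
#' @param post_s Silent tail simulated after the last frame (s, default
#'   0.7) so that late response lags are observable.
#' @return List with `rate_hz` (1 ms grid), `n_ms`, and `duration_s`.
#' @export
ln_rate <- function(trace, model, post_s = 0.7) {
  n_ms <- ceiling((trace_duration(trace) + post_s) * 1000)
  onsets <- .onset_idx(trace)
  roll_inc <- trace$roll_increment_deg
  lift_inc <- trace$lift_increment_cm
  drop <- !trace$presented
  if (any(drop)) {
    roll_inc[drop] <- 0
    lift_inc[drop] <- 0
  }
  if (model$side == "right") roll_inc <- -roll_inc
  x_roll <- numeric(n_ms)
  x_lift <- numeric(n_ms)
  x_roll[onsets] <- roll_inc
  x_lift[onsets] <- lift_inc
  u <- model$roll_gain * .conv_causal(x_roll, model$kernel) +
    model$lift_gain * .conv_causal(x_lift, model$kernel)
  rate <- pmin(model$rmax_hz, pmax(0, model$r0_hz + model$slope_hz * u))
  list(rate_hz = rate, n_ms = n_ms, duration_s = n_ms / 1000)
}

#' Draw a spike train from a rate series
#'
#' Bernoulli spiking per 1 ms bin with probability `min(rate * 0.001, 1)`
#' (at most one spike per bin, an implicit 1 ms refractory period); spike
#' times are bin centres. Uses R's global RNG stream.
#'
#' @param rate_hz Nonnegative rate series on the 1 ms grid.
#' @param ... Identifiers passed to [spike_train()].
#' @return A `spike_train` of duration `length(rate_hz) / 1000` s.
#' @export
draw_spikes <- function(rate_hz, ...) {
  stopifnot(all(rate_hz >= 0))
  p <- pmin(rate_hz * 0.001, 1)
  fired <- stats::runif(length(p)) < p
  spike_train((which(fired) - 0.5) / 1000, duration = length(p) / 1000, ...)
}

#' Default simulated-experiment configuration
#'
#' Mirrors the recording protocol: order-8 m-sequences extended to 400
#' impulses at 165 Hz, 8 trials per condition, nine conditions (Roll
#' 18/33/48; Roll 33 plus constant roll at +/-25 and +/-50 deg/s; Roll 33
#' plus lift at +/-50 cm/s), trial 2 of Roll 33 sharing one m-sequence
#' across neurons, and 12 neurons with alternating receptive-field sides.
#'
#' @param n_neurons Number of neurons (default 12).
#' @param n_trials Trials per condition per neuron (default 8).
#' @param conditions List of `flow_condition`s (default the nine above).
#' @param drop_prob Per-frame probability of a dropped frame (default 0).
#' @param seed Master seed.
#' @param neuron Template parameters for [ln_model()] as a named list
#'   (fields `roll_gain`, `lift_gain`, `r0_hz`, `slope_hz`, `rmax_hz`,
#'   `ttp_ms`, `half_width_ms`, `amplitude`).
#' @return A config list for [simulate_experiment()].
#' @export
default_config <- function(n_neurons = 12, n_trials = 8,
                           conditions = NULL, drop_prob = 0, seed = 1,
                           neuron = list()) {
  if (is.null(conditions)) {
    conditions <- list(
      flow_condition(0.18),
      flow_condition(0.33),
      flow_condition(0.48),
      flow_condition(0.33, constant_roll_dps = -25),
      flow_condition(0.33, constant_roll_dps = -50),
      flow_condition(0.33, constant_roll_dps = 25),
      flow_condition(0.33, constant_roll_dps = 50),
      flow_condition(0.33, constant_lift_cmps = 50),
      flow_condition(0.33, constant_lift_cmps = -50)
    )
  }
  nd <- list(roll_gain = 260, lift_gain = 60, r0_hz = 30, slope_hz = 1,
             rmax_hz = 300, ttp_ms = 18, half_width_ms = 12, amplitude = 1)
  nd[names(neuron)] <- neuron
  list(
    n_neurons = as.integer(n_neurons),
    n_trials = as.integer(n_trials),
    order = 8L,
    extended_length = 400L,
    shared_condition = "roll33",
    shared_trial = 2L,
    drop_prob = drop_prob,
    seed = seed,
    conditions = conditions,
    neuron = nd,
    screen = screen_geometry()
  )
}

.validate_config <- function(config) {
  for (f in c("n_neurons", "n_trials", "order", "extended_length",
              "shared_condition", "shared_trial", "drop_prob", "seed",
              "conditions", "neuron", "screen")) {
    if (is.null(config[[f]]))
      stop(sprintf("config field '%s' is missing", f), call. = FALSE)
  }
  if (config$n_neurons < 1) stop("config field 'n_neurons' must be >= 1",
                                 call. = FALSE)
  if (config$n_trials < 1) stop("config field 'n_trials' must be >= 1",
                                call. = FALSE)
  labels <- vapply(config$conditions, function(cc) cc$label, character(1))
  if (anyDuplicated(labels))
    stop("config field 'conditions' has duplicate labels", call. = FALSE)
  if (!config$shared_condition %in% labels)
    stop("config field 'shared_condition' not among condition labels",
         call. = FALSE)
  if (config$shared_trial < 1 || config$shared_trial > config$n_trials)
    stop("config field 'shared_trial' out of range", call. = FALSE)
  invisible(labels)
}

#' Simulate a full synthetic experiment
#'
#' Generates the complete dataset the recording protocol would produce:
#' for each neuron and condition, `n_trials` trials each driven by a unique
#' random m-sequence, except the shared trial (trial 2 of Roll 33), which
#' uses one common m-sequence across all neurons. Each trial is a
#' (`stimulus_trace`, `spike_train`) pair from a ground-truth LN neuron;
#' optional random frame drops are recorded in the frame log. A continuous
#' preferred-direction roll response (1 s at 50 deg/s) is also simulated per
#' neuron for the inclusion gate.
#'
#' @param config Configuration list from [default_config()].
#' @return An object of class `synthetic_dataset`: list with `neurons`
#'   (per-neuron `ln_model` ground truth and id), `trials` (list of trial
#'   records with `neuron_id`, `condition`, `trial`, `trace`, `train`,
#'   `mseq`), `preferred_roll_rate_hz` (named vector), `config`.
#' @export
simulate_experiment <- function(config = default_config()) {
  labels <- .validate_config(config)
  set.seed(config$seed)
  nd <- config$neuron
  kernel <- make_kernel(nd$amplitude, nd$ttp_ms, nd$half_width_ms)
  neurons <- lapply(seq_len(config$n_neurons), function(i) {
    side <- if (i %% 2L == 1L) "left" else "right"
    list(neuron_id = sprintf("n%02d", i),
         model = ln_model(kernel, roll_gain = nd$roll_gain,
                          lift_gain = nd$lift_gain, r0_hz = nd$r0_hz,
                          slope_hz = nd$slope_hz, rmax_hz = nd$rmax_hz,
                          side = side))
  })
  # one shared m-sequence for the designated trial, drawn once; every
  # other trial must use a distinct sequence (the protocol guarantees
  # uniqueness), so collisions among the finitely many circular shifts in
  # the catalog are redrawn
  shared_mseq <- random_msequence(config$order, label = "shared")
  used <- new.env(parent = emptyenv())
  assign(paste(shared_mseq$values, collapse = ""), TRUE, envir = used)
  draw_unique <- function() {
    for (i in 1:1000) {
      m <- random_msequence(config$order)
      key <- paste(m$values, collapse = "")
      if (!exists(key, envir = used, inherits = FALSE)) {
        assign(key, TRUE, envir = used)
        return(m)
      }
    }
    stop("could not draw a unique m-sequence; too many trials for the order",
         call. = FALSE)
  }
  trials <- list()
  pref_rates <- numeric(config$n_neurons)
  scr <- config$screen
  for (i in seq_along(neurons)) {
    nrn <- neurons[[i]]
    # continuous preferred-direction roll (1 s at 50 deg/s) for inclusion;
    # right-side neurons are probed with their own preferred direction
    pref_sign <- if (nrn$model$side == "left") 1 else -1
    n_frames <- round(scr$frame_rate_hz)
    cont <- compose_trace(rep(1L, n_frames),
                          flow_condition(0, constant_roll_dps = pref_sign * 50,
                                         label = "pref_roll"),
                          scr, analysis_length = n_frames)
    rr <- ln_rate(cont, nrn$model, post_s = 0)
    # steady-state response after the onset transient (first 100 ms removed)
    pref_rates[i] <- mean(rr$rate_hz[101:rr$n_ms])
    for (cond in config$conditions) {
      for (tr in seq_len(config$n_trials)) {
        shared <- cond$label == config$shared_condition &&
          tr == config$shared_trial
        mseq <- if (shared) shared_mseq else draw_unique()
        ext <- extend_circular(mseq, config$extended_length)
        # conditions and m-sequence polarity are defined in the
        # neuron-relative frame (+1 = preferred direction); the trace stored
        # with the trial is the screen-frame presentation, i.e. mirrored
        # for right-side neurons, so that every neuron experiences the same
        # neuron-relative sequence on the shared trial
        stim <- mirror_normalize(compose_trace(ext, cond, scr),
                                 nrn$model$side)
        if (config$drop_prob > 0)
          stim$presented <- stats::runif(length(ext)) >= config$drop_prob
        rate <- ln_rate(stim, nrn$model)
        train <- draw_spikes(rate$rate_hz, neuron_id = nrn$neuron_id,
                             condition = cond$label, trial = tr)
        trials[[length(trials) + 1L]] <- list(
          neuron_id = nrn$neuron_id, condition = cond$label, trial = tr,
          shared = shared, trace = stim, train = train, mseq = mseq
        )
      }
    }
  }
  names(pref_rates) <- vapply(neurons, function(n) n$neuron_id, character(1))
  structure(list(
    neurons = neurons,
    trials = trials,
    preferred_roll_rate_hz = pref_rates,
    condition_labels = labels,
    config = config
  ), class = "synthetic_dataset")
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("synthetic LN dataset: %d neurons x %d conditions x %d trials = %d trials\n",
              x$config$n_neurons, length(x$config$conditions),
              x$config$n_trials, length(x$trials)))
  invisible(x)
}

#' Select trials from a dataset
#'
#' @param dataset A `synthetic_dataset` (or the equivalent structure from
#'   [load_recordings()]).
#' @param neuron_id,condition,trial Optional filters.
#' @param shared `TRUE`/`FALSE` to keep only (non-)shared trials.
#' @return List of trial records.
#' @export
dataset_trials <- function(dataset, neuron_id = NULL, condition = NULL,
                           trial = NULL, shared = NULL) {
  keep <- vapply(dataset$trials, function(t) {
    (is.null(neuron_id) || t$neuron_id %in% neuron_id) &&
      (is.null(condition) || t$condition %in% condition) &&
      (is.null(trial) || t$trial %in% trial) &&
      (is.null(shared) || identical(t$shared, shared))
  }, logical(1))
  dataset$trials[keep]
}
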