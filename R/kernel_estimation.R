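# Impulse-response (kernel) extraction by cross-correlation of the stimulus
# m-sequence with the binned spike train, Gaussian smoothing, and extraction
# of the six kernel parameters, plus the shuffled-spike control.

#' Cross-correlate a stimulus trace with a binned spike train
#'
#' Estimates the linear kernel as
#' `h(tau) = (1/M) * sum_i s_i * y(t_i + tau)` where `s_i` are the +/-1
#' polarities of the final `analysis_length` (default 255) impulses of the
#' trace, `t_i` their onset samples on the 1 ms grid, `y` the spike-count
#' vector at 1 ms resolution, and `M` the number of impulses used. Only the
#' m-sequence polarity enters the stimulus regressor; any constant-flow
#' component of the condition is excluded by construction. Out-of-range
#' products are dropped (the normalisation by `M` is fixed).
#'
#' @param trace A `stimulus_trace`.
#' @param spike_vector Integer spike counts on the 1 ms grid (see
#'   [bin_spikes()]).
#' @param lag_range_ms Lag window, default `c(-200, 600)` ms.
#' @return List with `lags` (ms) and `values` (raw correlation, a.u.).
#' @export
cross_correlate <- function(trace, spike_vector, lag_range_ms = c(-200, 600)) {
  n <- length(trace$sign_sequence)
  m <- trace$analysis_length
  idx <- (n - m + 1L):n
  onsets <- .onset_idx(trace)[idx]
  signs <- trace$sign_sequence[idx]
  if (max(onsets) > length(spike_vector))
    stop("spike vector does not cover the analysed impulses", call. = FALSE)
  lags <- lag_range_ms[1]:lag_range_ms[2]
  ny <- length(spike_vector)
  # pad so every onset + lag indexes a (zero) sample; out-of-range products
  # are thereby dropped
  pad <- max(0L, -(min(onsets) + lags[1]) + 1L,
             max(onsets) + lags[length(lags)] - ny)
  y <- c(numeric(pad), spike_vector, numeric(pad))
  idx <- outer(onsets + pad, lags, "+")
  values <- colSums(signs * matrix(y[idx], nrow = length(onsets))) / m
  list(lags = lags, values = values)
}

# Gaussian smoothing with SD = window_ms, truncated at +/-3 SD, weights
# renormalised over the available support at the edges (area preserved for
# interior features). window_ms = 0 is the identity.
.gauss_smooth <- function(x, window_ms) {
  if (window_ms <= 0) return(x)
  half <- ceiling(3 * window_ms)
  w <- exp(-((-half):half)^2 / (2 * window_ms^2))
  n <- length(x)
  num <- stats::convolve(c(rep(0, half), x, rep(0, half)), w, type = "filter")
  den <- stats::convolve(c(rep(0, half), rep(1, n), rep(0, half)), w,
                         type = "filter")
  num / den
}

#' Average trial correlations and smooth into an impulse response
#'
#' Pointwise mean of per-trial raw correlation series (identical lag grids)
#' followed by Gaussian smoothing with SD `window_ms`, truncated at
#' +/-3 SD (the narrow 5 ms filter of the analysis; `window_ms = 0`
#' disables smoothing).
#'
#' @param correlations A single series from [cross_correlate()] or a list of
#'   them.
#' @param window_ms Gaussian SD in ms (default 5).
#' @return An object of class `impulse_response`: `lags`, `values`,
#'   `raw_mean` (unsmoothed mean), `window_ms`, `n_trials`.
#' @export
mean_smooth <- function(correlations, window_ms = 5) {
  if (!is.null(correlations$lags)) correlations <- list(correlations)
  if (length(correlations) == 0) stop("no correlation series", call. = FALSE)
  lags <- correlations[[1]]$lags
  for (cc in correlations)
    if (!identical(cc$lags, lags))
      stop("correlation series are on different lag grids", call. = FALSE)
  mat <- vapply(correlations, function(cc) cc$values,
                numeric(length(lags)))
  raw_mean <- if (is.matrix(mat)) rowMeans(mat) else mat
  structure(list(
    lags = lags,
    values = .gauss_smooth(raw_mean, window_ms),
    raw_mean = raw_mean,
    window_ms = window_ms,
    n_trials = length(correlations)
  ), class = "impulse_response")
}

#' @export
print.impulse_response <- function(x, ...) {
  cat(sprintf("impulse response: lags %d..%d ms, %d trial(s), %g ms smoothing\n",
              min(x$lags), max(x$lags), x$n_trials, x$window_ms))
  invisible(x)
}

# first linearly interpolated crossing of `level`, scanning from index
# `from` in direction `dir` (+1/-1); returns the lag (ms) or NA
.crossing <- function(lags, values, level, from, dir) {
  i <- from
  n <- length(values)
  while (i + dir >= 1 && i + dir <= n) {
    j <- i + dir
    if ((values[i] - level) * (values[j] - level) <= 0 &&
        values[i] != values[j]) {
      frac <- (level - values[i]) / (values[j] - values[i])
      return(lags[i] + frac * (lags[j] - lags[i]))
    }
    i <- j
  }
  NA_real_
}

#' Extract the six kernel parameters from an impulse response
#'
#' Definitions: amplitude = maximum of the smoothed impulse response over
#' nonnegative lags; TTP = lag of that maximum (earliest on ties);
#' half-width = distance between the two interpolated 50%-of-maximum
#' crossings bracketing the peak; decay = interpolated first crossing of
#' `amplitude / e` after the peak, minus TTP; return to baseline = computed
#' on the broadly (25 ms) re-smoothed mean correlation, the first lag after
#' TTP where the value re-enters the baseline mean +/- 2 SD band (baseline
#' = lags in `baseline_range_ms`), minus TTP. The spike rate during the
#' analysed impulses is supplied by the caller (see [estimate_kernel()]).
#'
#' If the response has no positive peak the parameters are returned as `NA`
#' with `defined = FALSE` rather than silently zero.
#'
#' @param ir An `impulse_response` (its `raw_mean` is used for the broad
#'   re-smoothing).
#' @param broad_window_ms Gaussian SD for the return-to-baseline smoothing
#'   (default 25 ms; 0 disables).
#' @param baseline_range_ms Lag window defining the baseline (default
#'   `c(-200, -10)` ms).
#' @param sd_floor_frac Floor on the baseline SD, as a fraction of the
#'   amplitude, guarding noiseless inputs (default 1e-6).
#' @param spike_rate_hz Mean spike rate over the analysed impulses (Hz);
#'   defaults to the value attached by [estimate_kernel()] when present.
#' @return An object of class `kernel_params`: list with `amplitude`,
#'   `ttp_ms`, `half_width_ms`, `decay_ms`, `return_to_baseline_ms`,
#'   `spike_rate_hz`, `defined`.
#' @export
extract_params <- function(ir, broad_window_ms = 25,
                           baseline_range_ms = c(-200, -10),
                           sd_floor_frac = 1e-6, spike_rate_hz = NULL) {
  if (is.null(spike_rate_hz))
    spike_rate_hz <- if (!is.null(ir$spike_rate_hz)) ir$spike_rate_hz
      else NA_real_
  lags <- ir$lags
  v <- ir$values
  pos <- which(lags >= 0)
  undefined <- function() structure(list(
    amplitude = NA_real_, ttp_ms = NA_real_, half_width_ms = NA_real_,
    decay_ms = NA_real_, return_to_baseline_ms = NA_real_,
    spike_rate_hz = spike_rate_hz, defined = FALSE
  ), class = "kernel_params")
  if (length(pos) == 0) return(undefined())
  amplitude <- max(v[pos])
  if (!is.finite(amplitude) || amplitude <= 0) return(undefined())
  peak_i <- pos[which.max(v[pos])]  # earliest lag on ties
  ttp <- lags[peak_i]
  left <- .crossing(lags, v, amplitude / 2, peak_i, -1L)
  right <- .crossing(lags, v, amplitude / 2, peak_i, +1L)
  half_width <- if (is.na(left) || is.na(right)) NA_real_ else right - left
  decay_at <- .crossing(lags, v, amplitude / exp(1), peak_i, +1L)
  decay <- if (is.na(decay_at)) NA_real_ else decay_at - ttp
  # return to baseline on the broadly smoothed raw mean correlation
  broad <- .gauss_smooth(ir$raw_mean, broad_window_ms)
  base_i <- which(lags >= baseline_range_ms[1] & lags <= baseline_range_ms[2])
  rtb <- NA_real_
  if (length(base_i) >= 2) {
    b_mean <- mean(broad[base_i])
    b_sd <- max(stats::sd(broad[base_i]), sd_floor_frac * amplitude)
    after <- which(lags > ttp)
    inside <- after[abs(broad[after] - b_mean) <= 2 * b_sd]
    if (length(inside) > 0) rtb <- lags[inside[1]] - ttp
  }
  structure(list(
    amplitude = amplitude, ttp_ms = ttp, half_width_ms = half_width,
    decay_ms = decay, return_to_baseline_ms = rtb,
    spike_rate_hz = spike_rate_hz, defined = TRUE
  ), class = "kernel_params")
}

#' @export
print.kernel_params <- function(x, ...) {
  cat(sprintf(
    "kernel params: amp %.4g, TTP %.1f ms, half-width %.1f ms, decay %.1f ms, RTB %.1f ms, rate %.1f Hz\n",
    x$amplitude, x$ttp_ms, x$half_width_ms, x$decay_ms,
    x$return_to_baseline_ms, x$spike_rate_hz))
  invisible(x)
}

#' Spike rate during the analysed impulses
#'
#' Mean firing rate over the span of the final `analysis_length` impulses of
#' the trace (one m-sequence period).
#'
#' @param trace A `stimulus_trace`.
#' @param train A `spike_train`.
#' @return Rate in Hz.
#' @export
spike_rate_analysed <- function(trace, train) {
  n <- length(trace$sign_sequence)
  t0 <- trace$frame_times_s[n - trace$analysis_length + 1L]
  t1 <- t0 + trace$analysis_length / trace$frame_rate_hz
  sum(train$times >= t0 & train$times < t1) / (t1 - t0)
}

#' Estimate a neuron-condition impulse response from trials
#'
#' Cross-correlates every trial, averages, smooths with the narrow Gaussian
#' filter, and attaches the mean spike rate during the analysed impulses.
#'
#' @param trials List of trial records (fields `trace`, `train`).
#' @param lag_range_ms Lag window (default `c(-200, 600)`).
#' @param window_ms Narrow smoothing SD (default 5 ms).
#' @return An `impulse_response` with an added `spike_rate_hz` field.
#' @export
estimate_kernel <- function(trials, lag_range_ms = c(-200, 600),
                            window_ms = 5) {
  if (length(trials) == 0) stop("no trials to estimate from", call. = FALSE)
  corrs <- lapply(trials, function(tr) {
    y <- bin_spikes(tr$train, 1)
    cross_correlate(tr$trace, y, lag_range_ms)
  })
  ir <- mean_smooth(corrs, window_ms)
  ir$spike_rate_hz <- mean(vapply(trials, function(tr)
    spike_rate_analysed(tr$trace, tr$train), numeric(1)))
  ir
}

#' Shuffled-spike control kernel
#'
#' Redraws the trial's `K` spike times uniformly over the stimulus duration
#' (spike count preserved) and re-runs the kernel estimate. Impulse
#' responses from shuffled trains are flat up to estimation noise,
#' confirming that structure in the real kernel is stimulus-locked.
#'
#' @param trace A `stimulus_trace`.
#' @param train A `spike_train`.
#' @param lag_range_ms,window_ms As in [estimate_kernel()].
#' @return An `impulse_response` from the shuffled train (single trial).
#' @export
shuffled_kernel <- function(trace, train, lag_range_ms = c(-200, 600),
                            window_ms = 5) {
  sh <- shuffle_train(train, trace)
  y <- bin_spikes(sh, 1)
  mean_smooth(cross_correlate(trace, y, lag_range_ms), window_ms)
}

#' Shuffle a spike train uniformly in time
#'
#' Redraws the train's `K` spike times uniformly, preserving the spike
#' count. By default the redraw support is the full trial (`"trial"`), so
#' that the shuffled train is uniform over everything the cross-correlation
#' can see; with `support = "stimulus"` spikes are redrawn over the
#' stimulus presentation span only, which leaves a stimulus-end edge in the
#' shuffled record whenever the trial extends past the presentation (see
#' the package vignette for why `"trial"` is the default).
#'
#' @param train A `spike_train`.
#' @param trace The trial's `stimulus_trace` (used for the `"stimulus"`
#'   support).
#' @param support `"trial"` (default) or `"stimulus"`.
#' @return A `spike_train` with the same spike count.
#' @export
shuffle_train <- function(train, trace, support = c("trial", "stimulus")) {
  support <- match.arg(support)
  dur <- if (support == "trial") train$duration
         else min(trace_duration(trace), train$duration)
  k <- length(train$times)
  spike_train(sort(stats::runif(k, 0, dur)), duration = train$duration,
              neuron_id = train$neuron_id, condition = train$condition,
              trial = train$trial)
}

#' Write an impulse response or a parameter table to CSV
#'
#' @param ir An `impulse_response`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kernel_csv <- function(ir, path) {
  utils::write.csv(data.frame(lag_ms = ir$lags, value = ir$values),
                   path, row.names = FALSE)
  invisible(path)
}

#' Convert kernel parameters to a one-row data frame
#'
#' @param params A `kernel_params`.
#' @param neuron_id,condition Identifiers for the row.
#' @return One-row data frame with the tidy parameter-table columns.
#' @export
params_row <- function(params, neuron_id = NA, condition = NA) {
  data.frame(
    neuron_id = neuron_id, condition = condition,
    amplitude = params$amplitude, ttp_ms = params$ttp_ms,
    half_width_ms = params$half_width_ms, decay_ms = params$decay_ms,
    return_to_baseline_ms = params$return_to_baseline_ms,
    spike_rate_hz = params$spike_rate_hz, defined = params$defined,
    stringsAsFactors = FALSE
  )
}
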