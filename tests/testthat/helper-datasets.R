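# Shared fixtures, built once per test run and memoised.

.fixture_env <- new.env(parent = emptyenv())

# Mirror-normalised dataset (traces in the neuron-relative frame).
normalized_dataset <- function(config) {
  ds <- simulate_experiment(config)
  sides <- vapply(ds$neurons, function(n) n$model$side, character(1))
  names(sides) <- vapply(ds$neurons, function(n) n$neuron_id, character(1))
  ds$trials <- lapply(ds$trials, function(t) {
    t$trace <- mirror_normalize(t$trace, sides[[t$neuron_id]])
    t
  })
  ds
}

# Default-parameter Roll 33 dataset (12 neurons x 8 trials), the protocol's
# core recording block; used by recovery and validation tests.
roll33_dataset <- function() {
  if (is.null(.fixture_env$roll33)) {
    .fixture_env$roll33 <- normalized_dataset(default_config(
      n_neurons = 12, conditions = list(flow_condition(0.33)), seed = 424242))
  }
  .fixture_env$roll33
}

# Small 4-neuron Roll 33 dataset for cheaper structural tests.
small_dataset <- function() {
  if (is.null(.fixture_env$small)) {
    .fixture_env$small <- normalized_dataset(default_config(
      n_neurons = 4, n_trials = 4,
      conditions = list(flow_condition(0.33)), seed = 99))
  }
  .fixture_env$small
}

# Noiseless frame-grid linear response for the cross-correlation oracle
# tests. A 200 Hz frame rate puts every onset on an exact 5 ms sample, so
# the m-sequence autocorrelation identity holds exactly on the 1 ms grid.
oracle_case <- function(order, h_frames) {
  scr <- screen_geometry(frame_rate_hz = 200)
  m <- generate_msequence(order, rollkernel:::.mseq_catalog[[
    as.character(order)]][[1]])
  n <- length(m$values)
  nf <- n + 16
  off <- (n - (nf %% n)) %% n
  xc <- function(f) m$values[((f - 1 + off) %% n) + 1]
  tr <- compose_trace(xc(seq_len(nf)), flow_condition(0.33), scr,
                      analysis_length = n)
  nfy <- nf + 8
  y <- numeric(nfy * 5 + 10)
  kmax <- length(h_frames) - 1
  for (f in seq_len(nfy))
    y[5 * (f - 1) + 1] <- sum(h_frames * xc(f - (0:kmax)))
  list(trace = tr, y = y, n = n)
}

# A triangular test impulse response with known closed-form parameters:
# 0 at 0 ms, 1 at 20 ms, back to 0 at 60 ms, flat after.
triangle_ir <- function() {
  lags <- -200:600
  v <- ifelse(lags < 0, 0,
              ifelse(lags <= 20, lags / 20,
                     ifelse(lags <= 60, 1 - (lags - 20) / 40, 0)))
  structure(list(lags = lags, values = v, raw_mean = v, window_ms = 0,
                 n_trials = 1), class = "impulse_response")
}
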