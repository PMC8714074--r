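# Ground-truth LN generator: kernels, rates, spiking and the full protocol

test_that("parametric kernels peak where and how wide they should", {
  k <- make_kernel(amplitude = 1, ttp_ms = 18, half_width_ms = 12)
  expect_equal(max(k), 1)
  expect_equal(which.max(k) - 1, 18)  # lag grid starts at 0
  # numeric FWHM scan with linear interpolation
  half <- 0.5
  above <- which(k >= half)
  lo <- min(above); hi <- max(above)
  left <- (lo - 1) - (k[lo] - half) / (k[lo] - k[lo - 1])
  right <- (hi - 1) + (k[hi] - half) / (k[hi] - k[hi + 1])
  expect_lt(abs((right - left) - 12), 0.5)
  # causal, and negligible beyond 150 ms
  expect_equal(k[1], 0)
  k300 <- make_kernel(length_ms = 300)
  expect_true(all(abs(k300[152:301]) < 0.01 * max(k300)))
  expect_error(make_kernel(ttp_ms = 400, length_ms = 300), "ttp")
})

test_that("the LN rate is linear below saturation and clipped above", {
  scr <- screen_geometry()
  set.seed(4)
  tr <- compose_trace(extend_circular(random_msequence(8), 400),
                      flow_condition(0.33), scr)
  zero <- ln_model(kernel = rep(0, 301), r0_hz = 30)
  expect_true(all(ln_rate(tr, zero)$rate_hz == 30))
  m1 <- ln_model(roll_gain = 20, rmax_hz = 1e6, r0_hz = 1e5)  # no clipping
  m2 <- ln_model(roll_gain = 40, rmax_hz = 1e6, r0_hz = 1e5)
  r1 <- ln_rate(tr, m1)$rate_hz - 1e5
  r2 <- ln_rate(tr, m2)$rate_hz - 1e5
  expect_equal(r2, 2 * r1, tolerance = 1e-9)
  msat <- ln_model(roll_gain = 1e9, rmax_hz = 300)
  expect_equal(max(ln_rate(tr, msat)$rate_hz), 300)
  expect_true(all(ln_rate(tr, ln_model())$rate_hz >= 0))
})

test_that("Bernoulli spiking matches its binomial expectation and seed", {
  expect_length(draw_spikes(rep(0, 1000))$times, 0)
  set.seed(8)
  n <- length(draw_spikes(rep(100, 10000))$times)  # 10 s at 100 Hz
  expect_lt(abs(n - 1000), 3 * sqrt(1000 * 0.1 * 0.9))
  set.seed(123)
  a <- draw_spikes(rep(50, 5000))
  set.seed(123)
  b <- draw_spikes(rep(50, 5000))
  expect_identical(a$times, b$times)
})

test_that("the simulated protocol has the right trial structure and shared m-sequence", {
  ds <- small_dataset()  # 4 neurons x 1 condition x 4 trials, normalised
  expect_length(ds$trials, 4 * 1 * 4)
  shared <- dataset_trials(ds, shared = TRUE)
  expect_length(shared, 4)
  expect_true(all(vapply(shared, function(t) t$trial == 2L, logical(1))))
  # identical neuron-relative sign sequence across neurons on the shared trial
  seqs <- lapply(shared, function(t) t$trace$sign_sequence)
  expect_length(unique(seqs), 1)
  # all other trials use distinct m-sequences
  others <- dataset_trials(ds, shared = FALSE)
  other_seqs <- lapply(others, function(t) t$mseq$values)
  expect_equal(length(unique(other_seqs)), length(others))
  # reproducible from the master seed
  ds2 <- normalized_dataset(ds$config)
  expect_identical(ds$trials[[5]]$train$times, ds2$trials[[5]]$train$times)
})

test_that("frame drops appear only when requested and invalid configs fail early", {
  cfg <- default_config(n_neurons = 1, n_trials = 2,
                        conditions = list(flow_condition(0.33)), seed = 1)
  ds <- simulate_experiment(cfg)
  expect_true(all(vapply(ds$trials, function(t) all(t$trace$presented),
                         logical(1))))
  cfg$drop_prob <- 0.05
  ds_drop <- simulate_experiment(cfg)
  expect_false(all(vapply(ds_drop$trials, function(t) all(t$trace$presented),
                          logical(1))))
  cfg_bad <- default_config(n_neurons = 0)
  expect_error(simulate_experiment(cfg_bad), "n_neurons")
  cfg_bad2 <- default_config()
  cfg_bad2$shared_condition <- "nope"
  expect_error(simulate_experiment(cfg_bad2), "shared_condition")
})

test_that("the simulated preferred-roll response sits at the reported mean rate", {
  ds <- small_dataset()
  expect_true(all(abs(ds$preferred_roll_rate_hz - 199) < 5))
})
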