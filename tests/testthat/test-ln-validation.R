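# LN-model validation: generator signal, nonlinearity, prediction,
# reference response and leave-one-out machinery

test_that("generator signal obeys the convolution identities", {
  tr <- compose_trace(c(1, rep(-1, 3), rep(1, 3)), flow_condition(0.33))
  n_ms <- 60
  expect_true(all(generator_signal(tr, rep(0, 50), n_ms) == 0))
  # unit-impulse kernel at lag 0 reproduces the impulse train
  g <- generator_signal(tr, c(1), n_ms)
  onsets <- floor(tr$frame_times_s * 1000 + 1e-6) + 1
  expect_equal(g[onsets], tr$sign_sequence)
  expect_lt(max(abs(g[-onsets])), 1e-9)  # FFT convolution residue only
  # single +1 impulse copies the kernel at the impulse time
  tr1 <- compose_trace(c(1), flow_condition(0.33))
  h <- c(0, 0.5, 1, 0.25)
  g1 <- generator_signal(tr1, h, 10)
  expect_equal(g1[1:4], h)
})

test_that("the binned nonlinearity recovers a two-level rate map", {
  set.seed(20)
  gen <- rep(c(-1, 1), each = 5000)[sample(10000)]
  rate <- ifelse(gen > 0, 100, 0)
  spikes <- rbinom(10000, 1, rate / 1000)
  nl <- fit_nonlinearity(gen, spikes, n_bins = 2)
  lo <- predict_nonlinearity(nl, -1)
  hi <- predict_nonlinearity(nl, 1)
  expect_equal(lo, 0, tolerance = 1e-12)
  expect_lt(abs(hi - 100), 3 * sqrt(100 * 1000 / 5000))
  # out-of-range values clamp to the edge bins
  expect_equal(predict_nonlinearity(nl, -100), lo)
  expect_equal(predict_nonlinearity(nl, 100), hi)
  # constant generator collapses to a single bin at the overall mean
  expect_warning(nlc <- fit_nonlinearity(rep(1, 1000), rbinom(1000, 1, 0.05),
                                         n_bins = 10), "merged")
  expect_length(nlc$rates_hz, 1)
})

test_that("a monotone ground-truth nonlinearity is recovered monotonically", {
  set.seed(21)
  gen <- rnorm(60000)
  rate <- pmax(0, 50 + 40 * gen)
  spikes <- rbinom(length(gen), 1, pmin(rate / 1000, 1))
  nl <- fit_nonlinearity(gen, spikes, n_bins = 10)
  # allow small non-monotone jitter between adjacent bins
  expect_gt(cor(seq_along(nl$rates_hz), nl$rates_hz, method = "spearman"),
            0.95)
})

test_that("reference response sums trains linearly and the sliding mean shrinks at edges", {
  t1 <- spike_train(c(0.1, 0.2), 1)
  t2 <- spike_train(c(0.5), 1)
  rAB <- reference_response(list(t1, t2), n_ms = 1000, window_ms = 1)
  rA <- reference_response(list(t1), n_ms = 1000, window_ms = 1)
  rB <- reference_response(list(t2), n_ms = 1000, window_ms = 1)
  expect_equal(rAB, rA + rB)
  expect_true(all(reference_response(list(spike_train(numeric(0), 1)),
                                     n_ms = 100) == 0))
  # shrinking edge windows still average correctly
  x <- c(1, 2, 3, 4, 5)
  expect_equal(sliding_mean(x, 3), c(1.5, 2, 3, 4, 4.5))
  expect_identical(sliding_mean(x, 1), x)
})

test_that("Pearson correlation is affine-invariant on the prediction scale", {
  set.seed(30)
  a <- sliding_mean(rnorm(500), 50)
  b <- sliding_mean(rnorm(500), 50)
  r0 <- cor(a, b)
  expect_equal(cor(3 * a + 7, b), r0, tolerance = 1e-12)
  expect_equal(cor(a, 0.1 * b - 2), r0, tolerance = 1e-12)
})

test_that("a true LN model predicts its own stimulus nearly perfectly", {
  ds <- small_dataset()
  model <- ds$neurons[[1]]$model
  sh <- dataset_trials(ds, neuron_id = "n01", shared = TRUE)[[1]]
  n_ms <- 2425
  true_rate <- ln_rate(sh$trace, model)$rate_hz[1:n_ms]
  # generator from the true kernel, nonlinearity fitted on the true rate
  gen <- model$roll_gain * 0.33 *
    generator_signal(sh$trace, model$kernel, n_ms)
  nl <- fit_nonlinearity(gen, true_rate / 1000, n_bins = 40)
  pred <- predict_nonlinearity(nl, gen)
  expect_gt(cor(pred, true_rate), 0.99)
  # flat nonlinearity gives a constant prediction
  flat <- nl
  flat$rates_hz[] <- 42
  expect_equal(unique(predict_nonlinearity(flat, gen)), 42)
})

test_that("leave-one-out predictions correlate with the held-out reference", {
  ds <- small_dataset()
  set.seed(61)
  v <- loo_correlations(ds)
  expect_length(v$per_neuron, 4)
  expect_true(all(v$per_neuron >= -1 & v$per_neuron <= 1))
  expect_gt(v$median_r, 0.5)
  one <- ds
  one$trials <- dataset_trials(ds, neuron_id = "n01")
  expect_error(loo_correlations(one), "at least 2")
})

test_that("the shared trial never leaks into training", {
  ds <- small_dataset()
  trs <- rollkernel:::.training_trials(ds, "n01", "roll33")
  expect_true(all(!vapply(trs, function(t) isTRUE(t$shared), logical(1))))
  expect_length(trs, ds$config$n_trials - 1)
})

test_that("the shuffle control is reproducible and near zero on a small dataset", {
  ds <- small_dataset()
  set.seed(71)
  sc <- shuffle_control(ds, n_shuffles = 4)
  set.seed(71)
  sc2 <- shuffle_control(ds, n_shuffles = 4)
  expect_identical(sc$per_neuron_mean, sc2$per_neuron_mean)
  expect_lt(abs(sc$median_r), 0.3)  # loose at 4 neurons x 4 shuffles
})
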