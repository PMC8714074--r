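# Cross-correlation kernel estimation, smoothing, parameter extraction and
# the shuffled-spike control

test_that("the estimator matches the closed form h(1 + 1/N) - sum(h)/N exactly (orders 3-8)", {
  h <- c(2, 1, 0.5)
  for (order in 3:8) {
    cs <- oracle_case(order, h)
    cc <- cross_correlate(cs$trace, cs$y, c(-50, 50))
    est <- cc$values[match(c(0, 5, 10), cc$lags)]
    expected <- h * (1 + 1 / cs$n) - sum(h) / cs$n
    expect_lt(max(abs(est - expected)), 1e-9)
    # off-support frame lags sit at -sum(h)/N
    expect_lt(abs(cc$values[match(15, cc$lags)] + sum(h) / cs$n), 1e-9)
  }
})

test_that("a pure delay shows up as a single peak at that lag", {
  cs <- oracle_case(8, c(1))
  # delay the response by 3 ms
  y <- c(numeric(3), cs$y)[seq_along(cs$y)]
  cc <- cross_correlate(cs$trace, y, c(-20, 20))
  expect_equal(cc$lags[which.max(cc$values)], 3)
})

test_that("the estimator is linear in the response and flat for constant input", {
  cs <- oracle_case(5, c(2, 1, 0.5))
  y1 <- cs$y
  set.seed(1)
  y2 <- rpois(length(y1), 0.05)
  c1 <- cross_correlate(cs$trace, y1)$values
  c2 <- cross_correlate(cs$trace, y2)$values
  c12 <- cross_correlate(cs$trace, 2 * y1 + 3 * y2)$values
  expect_equal(c12, 2 * c1 + 3 * c2, tolerance = 1e-9)
  # constant response: flat series at c * (sum of signs)/N = c/N
  const <- cross_correlate(cs$trace, rep(1, length(y1)), c(-10, 10))$values
  expect_equal(unique(round(const, 12)), 1 / cs$n)
  expect_error(cross_correlate(cs$trace, numeric(10)), "cover")
})

test_that("mean smoothing averages trials, preserves area, and window 0 is identity", {
  lags <- -50:50
  a <- list(lags = lags, values = as.numeric(lags == 0))
  b <- list(lags = lags, values = as.numeric(lags == 10))
  ir0 <- mean_smooth(a, window_ms = 0)
  expect_identical(ir0$values, a$values)
  ir <- mean_smooth(list(a, b), window_ms = 5)
  expect_equal(sum(ir$values), 1, tolerance = 1e-6)  # mean of two unit areas
  expect_equal(ir$n_trials, 2)
  irb <- mean_smooth(list(a, a), window_ms = 5)
  expect_equal(irb$values, mean_smooth(a, window_ms = 5)$values)
  expect_error(mean_smooth(list()), "no correlation")
  expect_error(mean_smooth(list(a, list(lags = -10:10, values = 0:20))),
               "different lag grids")
})

test_that("parameter extraction matches the closed form on the triangular kernel", {
  p <- extract_params(triangle_ir(), broad_window_ms = 0)
  expect_equal(p$amplitude, 1)
  expect_equal(p$ttp_ms, 20)
  expect_equal(p$half_width_ms, 30, tolerance = 1e-9)
  expect_equal(p$decay_ms, 40 * (1 - exp(-1)), tolerance = 1e-9)
  # falls back into the (zero-noise, floored-SD) baseline band at 60 ms
  expect_equal(p$return_to_baseline_ms, 40)
  expect_true(p$defined)
})

test_that("responses with no positive peak are flagged undefined, not zeroed", {
  ir <- triangle_ir()
  ir$values <- -ir$values
  ir$raw_mean <- ir$values
  p <- extract_params(ir, broad_window_ms = 0)
  expect_false(p$defined)
  expect_true(is.na(p$amplitude))
  expect_true(is.na(p$ttp_ms))
})

test_that("kernel estimation recovers the ground-truth TTP on synthetic neurons", {
  ds <- small_dataset()
  truth <- make_kernel()
  for (nid in c("n01", "n02")) {
    ir <- estimate_kernel(dataset_trials(ds, neuron_id = nid))
    p <- extract_params(ir)
    expect_lt(abs(p$ttp_ms - 18), 2 + 1e-9)
    sel <- ir$lags >= 0 & ir$lags <= 100
    expect_gt(cor(ir$values[sel], truth[1:101]), 0.9)
    expect_gt(p$spike_rate_hz, 5)
  }
})

test_that("shuffled-spike kernels are flat and preserve spike counts", {
  ds <- small_dataset()
  tr <- dataset_trials(ds, neuron_id = "n01", shared = FALSE)[[1]]
  set.seed(55)
  sh <- shuffle_train(tr$train, tr$trace)
  expect_length(sh$times, length(tr$train$times))
  set.seed(55)
  sh2 <- shuffle_train(tr$train, tr$trace)
  expect_identical(sh$times, sh2$times)
  # per-neuron shuffled kernels (all trials shuffled, then averaged, as in
  # the control analysis) are flat: no excursion beyond 4x their own SD,
  # while the real kernel's peak towers far above the same scale
  real <- estimate_kernel(dataset_trials(ds, neuron_id = "n01"))
  base <- real$lags < -10
  real_z <- (max(real$values) - mean(real$values[base])) /
    sd(real$values[base])
  expect_gt(real_z, 10)
  set.seed(56)
  for (nid in c("n01", "n02", "n03", "n04")) {
    trs <- dataset_trials(ds, neuron_id = nid)
    shuffled <- lapply(trs, function(t) {
      t$train <- shuffle_train(t$train, t$trace)
      t
    })
    irs <- estimate_kernel(shuffled)
    dev <- abs(irs$values - mean(irs$values))
    expect_lt(max(dev), 4 * sd(irs$values))
  }
})
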