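# Starfield geometry, world transforms, projection and trace composition

test_that("worlds have the right sphere count and are seed-reproducible", {
  set.seed(1)
  w <- make_world()
  expect_equal(nrow(w$positions), 6400)
  set.seed(1)
  w2 <- make_world()
  expect_identical(w$positions, w2$positions)
  set.seed(1)
  expect_equal(nrow(make_world(density_per_m3 = 0)$positions), 0)
  expect_error(make_world(cube_side_m = -1), "positive")
})

test_that("roll and lift transforms behave like rigid motions modulo the cube", {
  set.seed(2)
  w <- make_world()
  expect_equal(transform_world(w, 360, 0)$positions, w$positions,
               tolerance = 1e-9)
  expect_equal(transform_world(w, 0, 400)$positions, w$positions,
               tolerance = 1e-9)
  one <- w
  one$positions <- matrix(c(1, 0, 1), 1)
  rot <- transform_world(one, 90)
  expect_equal(as.numeric(rot$positions), c(0, 1, 1), tolerance = 1e-12)
  # measure preservation: occupancy of one octant stays ~ 1/8 under
  # repeated roll+lift
  wt <- w
  for (i in 1:20) wt <- transform_world(wt, 33.3, 17.7)
  frac <- mean(wt$positions[, 1] > 0 & wt$positions[, 2] > 0 &
                 wt$positions[, 3] > 0)
  expect_lt(abs(frac - 1 / 8), 0.02)
})

test_that("projection maps distance to brightness and rejects out-of-view spheres", {
  scr <- screen_geometry()
  w <- make_world(density_per_m3 = 0)
  p <- project_sphere(c(0, 0, 1), scr, w)
  expect_equal(p$gray, 94 / 194, tolerance = 1e-12)
  expect_equal(p$center_px, c(1280, 720))
  expect_equal(project_sphere(c(0, 0, 0.06), scr, w)$gray, 0)
  expect_null(project_sphere(c(0, 0, -1), scr, w))
  expect_null(project_sphere(c(0, 0, 0.05), scr, w))  # closer than 6 cm
  expect_null(project_sphere(c(0, 0, 2.5), scr, w))   # beyond 2 m: white
  # gray monotone nondecreasing, diameter nonincreasing with distance
  ds <- seq(0.1, 1.9, by = 0.2)
  proj <- lapply(ds, function(d) project_sphere(c(0, 0, d), scr, w))
  grays <- vapply(proj, `[[`, numeric(1), "gray")
  diams <- vapply(proj, `[[`, numeric(1), "diameter_px")
  expect_true(all(diff(grays) >= 0))
  expect_true(all(diff(diams) <= 0))
})

test_that("about 1200 of the default world's spheres are rendered", {
  set.seed(11)
  counts <- replicate(25, count_rendered(make_world()))
  expect_gt(mean(counts), 1080)
  expect_lt(mean(counts), 1320)
  w <- make_world(density_per_m3 = 0)
  expect_equal(count_rendered(w), 0)
  w$positions <- matrix(c(0, 0, 1), 1)
  expect_equal(count_rendered(w), 1)
})

test_that("trace composition applies the documented per-frame arithmetic", {
  scr <- screen_geometry()
  # Roll 33 with constant inhibitory roll at 50 deg/s: +1 frames move
  # 0.33 - 50/165 (prints as 0.03), -1 frames -0.63
  tr <- compose_trace(c(1, -1, 1), flow_condition(0.33, constant_roll_dps = -50), scr)
  expect_equal(tr$roll_increment_deg,
               c(1, -1, 1) * 0.33 - 50 / 165, tolerance = 1e-12)
  expect_equal(round(tr$roll_increment_deg[1], 2), 0.03)
  expect_equal(round(tr$roll_increment_deg[2], 2), -0.63)
  # pure Roll 33: exactly +/-0.33
  tr2 <- compose_trace(c(1, -1), flow_condition(0.33), scr)
  expect_identical(tr2$roll_increment_deg, c(0.33, -0.33))
  # lift at 50 cm/s: 0.303 cm per frame (prints as 0.3)
  tr3 <- compose_trace(c(1, 1), flow_condition(0.33, constant_lift_cmps = 50), scr)
  expect_equal(tr3$lift_increment_cm, rep(50 / 165, 2), tolerance = 1e-12)
  expect_equal(round(tr3$lift_increment_cm[1], 1), 0.3)
  expect_error(compose_trace(c(1, 2), flow_condition(0.33)), "\\+1/-1")
})

test_that("roll increment bookkeeping sums exactly over any window", {
  set.seed(12)
  m <- random_msequence(8)
  ext <- extend_circular(m, 400)
  cond <- flow_condition(0.33, constant_roll_dps = 25)
  tr <- compose_trace(ext, cond)
  for (win in list(1:50, 100:300, 1:400)) {
    expect_equal(sum(tr$roll_increment_deg[win]),
                 0.33 * sum(ext[win]) + 25 * length(win) / 165,
                 tolerance = 1e-9)
  }
})

test_that("traces survive a CSV round-trip", {
  tr <- compose_trace(c(1, -1, 1, 1), flow_condition(0.33, 25))
  f <- tempfile(fileext = ".csv")
  write_trace_csv(tr, f)
  tr2 <- read_trace_csv(f, tr$condition, analysis_length = tr$analysis_length)
  expect_equal(tr2$sign_sequence, tr$sign_sequence)
  expect_equal(tr2$roll_increment_deg, tr$roll_increment_deg)
  unlink(f)
})
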