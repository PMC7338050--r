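test_that("control background subtraction removes the mean control signal", {
  objs <- list(fake_cilium(1, c(10, 4)), fake_cilium(2, c(20, 6)),
               fake_cilium(3, c(30, 8)))
  # controls identical to the objects: channel means drop to zero on average
  out <- subtract_control_background(objs, objs, channel = 1)
  expect_equal(vapply(out, function(o) o$mean_intensity[[1]], numeric(1)),
               c(10, 20, 30) - 20)
  # zero-mean controls are the identity
  zero_ctrl <- list(fake_cilium(9, c(0, 0)))
  out2 <- subtract_control_background(objs, zero_ctrl, channel = 1)
  expect_equal(vapply(out2, function(o) o$mean_intensity[[1]], numeric(1)),
               c(10, 20, 30))
  # hand-computed 3-object case, controls with mean 5.5 in channel 2
  ctrl <- list(fake_cilium(4, c(0, 5)), fake_cilium(5, c(0, 6)))
  out3 <- subtract_control_background(objs, ctrl, channel = 2)
  expect_equal(vapply(out3, function(o) o$mean_intensity[[2]], numeric(1)),
               c(4, 6, 8) - 5.5)
  expect_error(subtract_control_background(objs, list(), 1), "nonempty")
})

test_that("expression gate is strictly below the 7.5 a.u. default", {
  objs <- list(fake_cilium(1, c(7.4)), fake_cilium(2, c(7.6)),
               fake_cilium(3, c(7.5)))
  kept <- gate_by_expression(objs, gate_params(gate_channel = 1))
  expect_equal(vapply(kept, function(o) o$id, integer(1)), 1L)
  # infinite threshold is the identity
  expect_length(gate_by_expression(objs, gate_params(1, Inf)), 3)
  # boundary scan on a 0.1-step intensity grid: the smallest excluded value
  # equals the default threshold
  grid <- lapply(seq_along(seq(0, 10, by = 0.1)), function(i)
    fake_cilium(i, c(seq(0, 10, by = 0.1)[i])))
  kept_v <- vapply(gate_by_expression(grid, gate_params(1)),
                   function(o) o$mean_intensity[[1]], numeric(1))
  excluded <- setdiff(seq(0, 10, by = 0.1), kept_v)
  expect_equal(min(excluded), 7.5)
})

test_that("gating and background subtraction commute when background is zero", {
  set.seed(111)
  objs <- lapply(1:20, function(i) fake_cilium(i, c(runif(1, 0, 15))))
  ctrl <- list(fake_cilium(99, c(0)))
  g <- gate_params(1, 7.5)
  a <- gate_by_expression(subtract_control_background(objs, ctrl, 1), g)
  b <- subtract_control_background(gate_by_expression(objs, g), ctrl, 1)
  expect_identical(a, b)
})

test_that("length normalization reports percent of the control mean", {
  expect_equal(normalize_lengths_to_control(3, c(2, 2)), 150)
  treated <- c(2, 4, 6)
  expect_equal(mean(normalize_lengths_to_control(treated, treated)), 100)
  set.seed(112)
  tr <- runif(30, 2, 8); ctl <- runif(25, 2, 8)
  expect_equal(normalize_lengths_to_control(tr, ctl), tr * 100 / mean(ctl))
  expect_error(normalize_lengths_to_control(tr, numeric(0)), "nonempty")
})

test_that("length-intensity fit matches closed-form OLS and flags degeneracy", {
  # exactly collinear points
  objs <- lapply(1:5, function(i) fake_cilium(i, c(i * 2), length_um = 1 + 3 * i * 2))
  # exact collinearity: the perfect-fit note from the slope test is expected
  fit <- suppressWarnings(length_intensity_fit(objs, 1))
  expect_equal(fit$slope, 3, tolerance = 1e-12)
  expect_equal(fit$intercept, 1, tolerance = 1e-12)
  expect_equal(fit$correlation, 1, tolerance = 1e-12)

  # noisy linear data against the closed-form estimator
  set.seed(113)
  x <- runif(60, 0, 20)
  y <- 0.15 * x + 3 + rnorm(60, 0, 0.4)
  objs2 <- lapply(seq_along(x), function(i) fake_cilium(i, c(x[i]), y[i]))
  fit2 <- length_intensity_fit(objs2, 1)
  beta_hat <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  se <- sqrt(sum((y - mean(y) - beta_hat * (x - mean(x)))^2 / (60 - 2)) /
               sum((x - mean(x))^2))
  expect_equal(fit2$slope, beta_hat, tolerance = 1e-12)
  expect_lt(abs(fit2$slope - 0.15), 2 * se)
  expect_lt(fit2$p_value, 1e-4)

  const <- lapply(1:5, function(i) fake_cilium(i, c(5), length_um = i))
  expect_error(length_intensity_fit(const, 1), "constant")
  expect_error(length_intensity_fit(objs2[1:2], 1), "at least 3")
})

test_that("tracking links stationary objects and never swaps distant ones", {
  ob_at <- function(id, z, y, x, int = 100)
    fake_cilium(id, c(int), centroid = c(z, y, x))
  # one stationary object across 10 frames -> one 10-row track
  frames <- lapply(1:10, function(f) list(ob_at(1, 1, 2, 3)))
  tr <- track_over_time(frames)
  expect_equal(nrow(tr), 10)
  expect_equal(unique(tr$track_id), 1L)

  # two objects 10 um apart: two tracks, never swapped
  frames2 <- lapply(1:8, function(f)
    list(ob_at(1, 0, 0, 0, int = 50), ob_at(2, 0, 0, 10, int = 200)))
  tr2 <- track_over_time(frames2)
  expect_equal(length(unique(tr2$track_id)), 2)
  for (id in unique(tr2$track_id)) {
    expect_equal(length(unique(tr2$mean_int_1[tr2$track_id == id])), 1)
  }

  # disappearance ends the track; reappearance past the radius starts a new one
  frames3 <- c(lapply(1:5, function(f) list(ob_at(1, 0, 0, 0))),
               list(list()),
               lapply(7:10, function(f) list(ob_at(1, 0, 0, 0))))
  tr3 <- track_over_time(frames3)
  expect_equal(max(tr3$frame[tr3$track_id == 1]), 5)
  expect_equal(length(unique(tr3$track_id)), 2)

  # conservation: every observation belongs to exactly one track
  expect_equal(nrow(tr3), 9)
})

test_that("tracking respects the maximum displacement radius", {
  ob_at <- function(id, x) fake_cilium(id, c(1), centroid = c(0, 0, x))
  frames <- list(list(ob_at(1, 0)), list(ob_at(1, 1)), list(ob_at(1, 5)))
  tr <- track_over_time(frames, max_displacement_um = 2)
  expect_equal(length(unique(tr$track_id)), 2)  # the 4-um jump breaks the track
})
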