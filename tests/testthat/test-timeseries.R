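test_that("background subtraction is exact and elementwise", {
  v <- cbind(a = c(10, 12, 14), b = c(5, 5, 8))
  tr <- ts_trace(v, stimulus_frame = 3)
  expect_equal(background_subtract(tr, 0)$values, v)          # identity
  expect_true(all(background_subtract(ts_trace(cbind(a = rep(7, 4)),
                                               stimulus_frame = 4),
                                      7)$values == 0))
  got <- background_subtract(tr, c(2, 3))$values
  expect_equal(unname(got), unname(v) - rep(c(2, 3), each = 3))
})

test_that("FRET bleed-through correction is the printed linear formula", {
  expect_equal(fret_bleedthrough_correct(100, 40, 50), 69)
  # alpha = beta = 0 and zero contaminators are identities
  expect_equal(fret_bleedthrough_correct(123.4, 99, 77,
                                         bleedthrough_params(0, 0)), 123.4)
  expect_equal(fret_bleedthrough_correct(123.4, 0, 0), 123.4)
  # defaults carry the published constants
  p <- bleedthrough_params()
  expect_equal(p$alpha, 0.75)
  expect_equal(p$beta, 0.02)
  # linearity: scaling (alpha, cerulean) by (k, 1/k) leaves the result fixed
  k <- 3.7
  expect_equal(
    fret_bleedthrough_correct(50, 8 / k, 5, bleedthrough_params(0.75 * k, 0.02)),
    fret_bleedthrough_correct(50, 8, 5))
})

test_that("bleed-through estimation recovers a planted slope", {
  set.seed(91)
  donor <- runif(50, 10, 100)
  leak <- 0.75 * donor
  expect_equal(estimate_bleedthrough(leak, donor), 0.75, tolerance = 1e-12)
  leak_noisy <- leak + rnorm(50, 0, 0.5)
  expect_equal(estimate_bleedthrough(leak_noisy, donor), 0.75,
               tolerance = 0.02)
})

test_that("ratio traces flag zero-denominator frames instead of infinities", {
  expect_equal(ratio_trace(c(1, 2, 3), c(1, 2, 3)),
               c(1, 1, 1), ignore_attr = TRUE)
  r <- ratio_trace(c(1, 2, 3), c(1, 0, 3))
  expect_true(is.na(r[2]))
  expect_equal(attr(r, "invalid_frames"), 2L)
  set.seed(92)
  num <- runif(20); den <- runif(20) + 0.5
  expect_equal(as.numeric(ratio_trace(num, den)), num / den)
})

test_that("baseline normalization fixes the baseline mean at 1 and is idempotent", {
  tr <- ts_trace(c(2, 2, 3), stimulus_frame = 3)
  expect_equal(as.numeric(baseline_normalize(tr)$values), c(1, 1, 1.5))
  cst <- ts_trace(rep(4.2, 6), stimulus_frame = 4)
  expect_true(all(baseline_normalize(cst)$values == 1))

  set.seed(93)
  tr2 <- ts_trace(cbind(a = runif(30, 5, 10), b = runif(30, 1, 2)),
                  stimulus_frame = 25)
  n1 <- baseline_normalize(tr2)
  expect_lt(abs(mean(n1$values[1:24, "a"]) - 1), 1e-12)
  expect_lt(abs(mean(n1$values[1:24, "b"]) - 1), 1e-12)
  n2 <- baseline_normalize(n1)
  expect_equal(n2$values, n1$values, tolerance = 1e-12)

  zero <- ts_trace(c(0, 0, 5), stimulus_frame = 3)
  expect_error(baseline_normalize(zero), "baseline mean")
})

test_that("trace operations preserve frame count and times", {
  set.seed(94)
  tr <- ts_trace(cbind(a = runif(10, 2, 4)), frame_times = seq(0, 45, by = 5),
                 stimulus_frame = 6)
  for (out in list(background_subtract(tr, 1), baseline_normalize(tr))) {
    expect_equal(nrow(out$values), 10)
    expect_equal(out$frame_times, tr$frame_times)
    expect_equal(out$stimulus_frame, tr$stimulus_frame)
  }
})

test_that("plate-reader normalization anchors baseline at 0 and ionomycin at 1", {
  expect_equal(plate_reader_normalize(500, 100, 500, positive_fraction = 1), 1)
  expect_equal(plate_reader_normalize(100, 100, 500, positive_fraction = 1), 0)
  expect_equal(plate_reader_normalize(100, 100, 500), 0)  # fraction omitted
  # halving the positive fraction doubles the output
  expect_equal(plate_reader_normalize(300, 100, 500, positive_fraction = 0.5),
               2 * plate_reader_normalize(300, 100, 500, positive_fraction = 1))
  expect_error(plate_reader_normalize(300, 100, 100), "must differ")
})

test_that("default baseline window is every frame before the stimulus", {
  tr <- ts_trace(runif(30), frame_times = seq(0, by = 5, length.out = 30),
                 stimulus_frame = 25)
  expect_equal(tr$baseline_window, 1:24)
  expect_error(ts_trace(runif(5), stimulus_frame = 1), "baseline_window")
})
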