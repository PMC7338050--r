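test_that("max projection equals a per-pixel loop over z", {
  set.seed(11)
  v <- array(runif(4 * 8 * 8) * 100, dim = c(4, 8, 8))
  s <- make_stack(v)
  proj <- max_project(s, 1)
  ref <- matrix(0, 8, 8)
  for (y in 1:8) for (x in 1:8) ref[y, x] <- max(v[, y, x])
  expect_equal(proj, ref)

  # single-slice stack projects to itself; constant volume stays constant
  s1 <- make_stack(array(v[2, , ], dim = c(1, 8, 8)))
  expect_equal(max_project(s1, 1), v[2, , ])
  sc <- make_stack(array(7, dim = c(3, 4, 4)))
  expect_true(all(max_project(sc, 1) == 7))
})

test_that("Renyi threshold matches the exhaustive-scan oracle on seeded histograms", {
  # bimodal mixture from the classical two-population case
  set.seed(3)
  x <- c(rnorm(1000, 50, 10), rnorm(1000, 200, 10))
  h <- build_histogram(x)
  expect_identical(attr(renyi_entropy_threshold(h), "bin"),
                   naive_renyi_bin(h$counts))

  # uniform histogram: deterministic lowest-index tie-breaks inside orders
  hu <- build_histogram(rep(0:255, each = 4))
  expect_identical(attr(renyi_entropy_threshold(hu), "bin"),
                   naive_renyi_bin(hu$counts))

  # 25 seeded random histogram shapes
  for (s in 1:25) {
    set.seed(400 + s)
    n_modes <- sample(1:3, 1)
    x <- unlist(lapply(seq_len(n_modes), function(i)
      rnorm(sample(100:800, 1), runif(1, 10, 240), runif(1, 3, 40))))
    x <- pmin(pmax(x, 0), 255)
    h <- build_histogram(x)
    if (sum(h$counts > 0) < 2) next
    expect_identical(attr(renyi_entropy_threshold(h), "bin"),
                     naive_renyi_bin(h$counts),
                     label = paste("seed", 400 + s))
  }
})

test_that("two-point histograms separate and degenerate ones error", {
  h2 <- build_histogram(c(rep(0, 50), rep(255, 50)))
  thr <- renyi_entropy_threshold(h2)
  expect_gt(thr, 0)
  expect_lt(thr, 255)

  expect_error(renyi_entropy_threshold(build_histogram(rep(42, 100))),
               "fewer than 2 occupied bins")
})

test_that("threshold depends only on the histogram, never on pixel positions", {
  set.seed(21)
  x <- c(rnorm(500, 60, 15), rnorm(500, 180, 20))
  x <- pmin(pmax(x, 0), 255)
  h1 <- build_histogram(x)
  h2 <- build_histogram(sample(x))
  expect_identical(renyi_entropy_threshold(h1), renyi_entropy_threshold(h2))
})

test_that("well-separated bimodal thresholds fall strictly between the modes", {
  for (s in 1:10) {
    set.seed(500 + s)
    m1 <- runif(1, 20, 80)
    m2 <- m1 + runif(1, 60, 150)
    x <- pmin(pmax(c(rnorm(800, m1, 1.2), rnorm(800, m2, 1.2)), 0), 255)
    h <- build_histogram(x)
    thr <- renyi_entropy_threshold(h)
    expect_gt(thr, m1 + 3)
    expect_lt(thr, m2 - 3)
  }
})

test_that("apply_threshold is a strict elementwise comparison", {
  set.seed(31)
  v <- array(sample(0:50, 3 * 6 * 6, replace = TRUE), dim = c(3, 6, 6))
  s <- make_stack(v)
  m <- apply_threshold(s, 1, 20)
  ref <- array(FALSE, dim(v))
  for (i in seq_along(v)) ref[i] <- v[i] > 20
  expect_identical(m$foreground, ref)
  # boundary: threshold at the max leaves nothing; below the min takes all
  expect_false(any(apply_threshold(s, 1, max(v))$foreground))
  expect_true(all(apply_threshold(s, 1, min(v) - 1)$foreground))
})

test_that("segment_marker covers bright tubes and is intensity-scale invariant", {
  spec <- synthetic_spec(n_cilia = 2, psf_sigma = 0,
                         noise = list(gaussian_sd = 0, poisson = FALSE),
                         background_level = 5, seed = 77)
  f <- generate_cilium_field(spec)
  m <- segment_marker(f$stack)
  truth_fg <- array(FALSE, dim(m$foreground))
  for (tr in f$truth) truth_fg[tr$footprint] <- TRUE
  expect_true(all(m$foreground[truth_fg]))           # tubes fully covered
  expect_lt(mean(m$foreground[!truth_fg]), 0.01)     # background < 1 % fg

  # doubling intensities then rescaling to the original range leaves the
  # histogram shape, hence the mask, unchanged
  s2 <- f$stack
  v <- s2$voxels * 2
  v <- (v - min(v)) / (max(v) - min(v)) * max(f$stack$voxels)
  s2$voxels <- v
  m2 <- segment_marker(s2)
  expect_identical(m$foreground, m2$foreground)

  # all-zero stack: no separation possible
  zero <- make_stack(array(0, dim = c(2, 4, 4)))
  expect_error(segment_marker(zero), "occupied bin")
})

test_that("foreground is monotonically non-increasing in the threshold", {
  set.seed(41)
  v <- array(runif(4 * 10 * 10) * 100, dim = c(4, 10, 10))
  s <- make_stack(v)
  counts <- vapply(seq(0, 100, by = 10), function(thr)
    sum(apply_threshold(s, 1, thr)$foreground), numeric(1))
  expect_true(all(diff(counts) <= 0))
})
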