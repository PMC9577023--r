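# Fiber dynamics: sliding-window arithmetic, epoch branching, coverage.

test_that("fiber parameter contracts hold", {
  expect_error(fiber_params(0, 10), "n_fibers")
  expect_error(fiber_params(3, 10, window_len = 20, shift = 30), "shift")
  expect_error(fiber_params(3, 0), "iters_per_epoch")
  # shift = window_len (fast advance) and shift < window_len (crawl) allowed
  expect_s3_class(fiber_params(3, 10, window_len = 50, shift = 50),
                  "fiber_params")
  expect_s3_class(fiber_params(3, 10, window_len = 50, shift = 10),
                  "fiber_params")
})

test_that("backing-path horizon covers the epoch exactly", {
  # regression benchmark: 50 iterations, L = s = 50, dt = 1/500 -> T = 5
  p3 <- fiber_params(12, 50)
  expect_identical(p3$points_per_epoch, 2501L)
  expect_equal(p3$fbm$t_max, 5)
  # image benchmark: 16 iterations -> 801 points, T = 1.6 (within the
  # stated T = 2 budget)
  p4 <- fiber_params(60, 16)
  expect_identical(p4$points_per_epoch, 801L)
  expect_equal(p4$fbm$t_max, 1.6)
  # last window indices stay inside the path for both configurations
  for (p in list(p3, p4)) {
    last <- (p$iters_per_epoch - 1) * p$shift + p$window_len + 1
    expect_lte(last, p$points_per_epoch)
    fibers <- init_fibers(p, seed = 1)
    expect_silent(active_points(fibers, p$iters_per_epoch - 1L))
  }
})

test_that("consecutive windows share the predicted points", {
  shared_rows <- function(shift) {
    p <- fiber_params(1, 10, window_len = 50, shift = shift, dt = 1 / 500)
    fibers <- init_fibers(p, seed = 3)
    a0 <- active_points(fibers, 0)
    a1 <- active_points(fibers, 1)
    sum(apply(a1[, c("x", "y")], 1, function(q)
      any(abs(a0[, "x"] - q[1]) < 1e-12 & abs(a0[, "y"] - q[2]) < 1e-12)))
  }
  # s = L: the new window starts where the old one ended - 1 shared point
  expect_equal(shared_rows(50), 1)
  # s < L: crawling retains L - s + 1 previously occupied points
  expect_equal(shared_rows(10), 41)
})

test_that("iteration 0 starts at the fiber origin and over-running errors", {
  p <- fiber_params(2, 5, window_len = 10, shift = 10)
  fibers <- init_fibers(p, seed = 7)
  a0 <- active_points(fibers, 0)
  expect_equal(unname(a0[1, c("x", "y")]),
               unname(fibers$paths[[1]][1, ] %% 1))
  expect_error(active_points(fibers, 5), "branch")
  expect_error(active_points(fibers, -1), "iteration")
})

test_that("initialization and branching are reproducible under a seed", {
  p <- fiber_params(4, 6, window_len = 8, shift = 8)
  f1 <- init_fibers(p, seed = 13)
  f2 <- init_fibers(p, seed = 13)
  expect_identical(f1$paths, f2$paths)
  expect_false(identical(init_fibers(p, seed = 14)$paths, f1$paths))
  b1 <- branch_epoch(f1)
  b2 <- branch_epoch(f2)
  expect_identical(b1$paths, b2$paths)
  expect_identical(b1$epoch, 2L)
})

test_that("a branched fiber restarts inside its final window", {
  p <- fiber_params(5, 8, window_len = 12, shift = 12)
  fibers <- init_fibers(p, seed = 23)
  last <- active_points(fibers, p$iters_per_epoch - 1L)
  branched <- branch_epoch(fibers)
  for (f in seq_len(p$n_fibers)) {
    new_start <- branched$paths[[f]][1, ] %% 1
    win <- last[last[, "fiber"] == f, c("x", "y"), drop = FALSE]
    hit <- any(abs(win[, 1] - new_start[1]) < 1e-12 &
               abs(win[, 2] - new_start[2]) < 1e-12)
    expect_true(hit)
  }
})

test_that("fibers eventually visit every neuron of the layer", {
  # benchmark-scale run: N = 10, 12 superdiffusive fibers, 50 epochs of 50
  # iterations; with periodic wrap no neuron is unreachable
  sim <- simulate_drop_rates(neuron_grid(10), fiber_params(12, 50),
                             n_epochs = 50, seed = 17)
  expect_true(all(sim$neuron_drops > 0))
  expect_identical(sim$n_iterations, 2500L)
})

test_that("trajectory export covers the schedule", {
  p <- fiber_params(2, 3, window_len = 5, shift = 5)
  df <- fiber_trajectories(p, n_epochs = 2, seed = 5)
  expect_named(df, c("epoch", "iteration", "fiber", "x", "y"))
  expect_equal(nrow(df), 2 * 3 * 2 * 6)  # epochs x iters x fibers x (L+1)
  expect_true(all(df$x >= 0 & df$x < 1 & df$y >= 0 & df$y < 1))
})
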