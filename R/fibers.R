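# Fiber dynamics: each "fiber" is a sliding window over a long 2-D FBM
# backing path. At training iteration i (0-based) the fiber occupies the
# L + 1 path points with indices i*s ... i*s + L, i.e. the closed time
# interval [(i*s)*dt, (i*s + L)*dt]. With s = L the window advances fast and
# starts where it ended; with s < L it "crawls", retaining L - s + 1 points.
# At the end of each epoch every fiber branches: a fresh FBM path starts at
# a uniformly chosen point of the final window and the old path degenerates.
# Backing paths are generated unwrapped (so the wrap never distorts the FBM
# covariance); coordinates are wrapped periodically only when queried.

#' Fiber population parameters
#'
#' @param n_fibers Number of fibers n (positive integer). More fibers give a
#'   higher average drop rate.
#' @param iters_per_epoch Training iterations per epoch covered by one
#'   backing path before branching.
#' @param window_len Fiber "length" L in path points advanced per window;
#'   the active window holds L + 1 points (closed interval).
#' @param shift Points s the window advances per iteration; `shift <=
#'   window_len` (equality = fast advance, less = crawling).
#' @param hurst,sigma,dt FBM parameters of the backing paths (defaults:
#'   superdiffusive H = 0.9, sigma = 1, dt = 1/500).
#' @return An object of class `fiber_params`. The backing-path horizon is
#'   derived as `(iters_per_epoch - 1) * shift + window_len` steps, exactly
#'   covering the epoch's windows.
#' @examples
#' fiber_params(n_fibers = 12, iters_per_epoch = 50)  # regression benchmark
#' @export
fiber_params <- function(n_fibers, iters_per_epoch, window_len = 50L,
                         shift = 50L, hurst = 0.9, sigma = 1, dt = 1 / 500) {
  int1 <- function(x, nm, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x) ||
        x < min)
      stop_field(nm, sprintf("must be a single integer >= %d", min))
    as.integer(x)
  }
  n_fibers <- int1(n_fibers, "n_fibers")
  iters_per_epoch <- int1(iters_per_epoch, "iters_per_epoch")
  window_len <- int1(window_len, "window_len")
  shift <- int1(shift, "shift")
  if (shift > window_len)
    stop_field("shift", "must not exceed window_len (gaps in path usage)")
  n_steps <- (iters_per_epoch - 1L) * shift + window_len
  fbm <- fbm_params(hurst = hurst, sigma = sigma, t_max = n_steps * dt,
                    dt = dt)
  structure(
    list(n_fibers = n_fibers, iters_per_epoch = iters_per_epoch,
         window_len = window_len, shift = shift, fbm = fbm,
         points_per_epoch = n_steps + 1L),
    class = "fiber_params"
  )
}

#' @export
print.fiber_params <- function(x, ...) {
  cat(sprintf(
    "%d fibers: L = %d, s = %d, %d iters/epoch; FBM H = %g, dt = %g (T = %g)\n",
    x$n_fibers, x$window_len, x$shift, x$iters_per_epoch, x$fbm$hurst,
    x$fbm$dt, x$fbm$t_max))
  invisible(x)
}

fiber_backing_path <- function(params, origin, seed) {
  fbm_2d(params$fbm, origin = origin, seed = seed)$values
}

#' Initialize a population of fibers
#'
#' Each fiber gets an independent unwrapped 2-D FBM backing path starting at
#' a uniform-random point of the unit square. All randomness derives
#' deterministically from `seed` (per-fiber, per-epoch substreams), so runs
#' are reproducible.
#'
#' @param params A [fiber_params()] object.
#' @param seed Integer master seed, or `NULL` for ambient RNG.
#' @return An object of class `fiber_set`.
#' @export
init_fibers <- function(params, seed = NULL) {
  stopifnot(inherits(params, "fiber_params"))
  n <- params$n_fibers
  origins <- with_seed(derive_seed(seed, "origins"),
                       matrix(stats::runif(2L * n), ncol = 2L))
  paths <- lapply(seq_len(n), function(f) {
    fiber_backing_path(params, origins[f, ], derive_seed(seed, 1L, f))
  })
  structure(
    list(params = params, seed = seed, epoch = 1L, paths = paths),
    class = "fiber_set"
  )
}

#' @export
print.fiber_set <- function(x, ...) {
  cat(sprintf("Fiber set: %d fibers, epoch %d, %d path points each\n",
              x$params$n_fibers, x$epoch, x$params$points_per_epoch))
  print(x$params)
  invisible(x)
}

#' Active fiber points at a training iteration
#'
#' Returns the wrapped coordinates of every fiber's current window: path
#' points `i*s ... i*s + L` (0-based `iteration` i), wrapped into
#' `[0, 1)^2`.
#'
#' @param fibers A [init_fibers()] fiber set.
#' @param iteration 0-based iteration index within the current epoch, in
#'   `0 ... iters_per_epoch - 1`.
#' @return A matrix with columns `fiber`, `x`, `y`;
#'   `n_fibers * (window_len + 1)` rows.
#' @export
active_points <- function(fibers, iteration) {
  stopifnot(inherits(fibers, "fiber_set"))
  p <- fibers$params
  if (!is.numeric(iteration) || length(iteration) != 1L ||
      iteration != round(iteration) || iteration < 0)
    stop_field("iteration", "must be a single non-negative integer")
  if (iteration >= p$iters_per_epoch)
    stop(sprintf(
      "iteration %d exceeds this epoch's coverage (%d iterations); call branch_epoch() first",
      as.integer(iteration), p$iters_per_epoch), call. = FALSE)
  idx <- as.integer(iteration) * p$shift + seq_len(p$window_len + 1L)
  m <- p$window_len + 1L
  out <- matrix(0, nrow = p$n_fibers * m, ncol = 3L,
                dimnames = list(NULL, c("fiber", "x", "y")))
  for (f in seq_len(p$n_fibers)) {
    rows <- (f - 1L) * m + seq_len(m)
    out[rows, 1L] <- f
    out[rows, 2:3] <- fibers$paths[[f]][idx, , drop = FALSE] %% 1
  }
  out
}

#' Branch all fibers at the end of an epoch
#'
#' Each fiber initiates a fresh FBM backing path at a point drawn uniformly
#' from the `window_len + 1` points of its final window; the previous path
#' degenerates (is discarded) and the epoch counter increments.
#'
#' @param fibers A `fiber_set`.
#' @return The branched `fiber_set`.
#' @export
branch_epoch <- function(fibers) {
  stopifnot(inherits(fibers, "fiber_set"))
  p <- fibers$params
  next_epoch <- fibers$epoch + 1L
  last_idx <- (p$iters_per_epoch - 1L) * p$shift + seq_len(p$window_len + 1L)
  picks <- with_seed(
    derive_seed(fibers$seed, "branch", next_epoch),
    sample.int(p$window_len + 1L, p$n_fibers, replace = TRUE))
  fibers$paths <- lapply(seq_len(p$n_fibers), function(f) {
    start <- fibers$paths[[f]][last_idx[picks[f]], ] %% 1
    fiber_backing_path(p, start, derive_seed(fibers$seed, next_epoch, f))
  })
  fibers$epoch <- next_epoch
  fibers
}

#' Export fiber window positions over a schedule as a data frame
#'
#' Runs the fiber set over `n_epochs` epochs (branching between epochs) and
#' records every active point: columns `epoch`, `iteration` (0-based within
#' epoch), `fiber`, `x`, `y`. Reproduces the raw material of fiber-dynamics
#' animations.
#'
#' @param params A [fiber_params()].
#' @param n_epochs Number of epochs to simulate.
#' @param seed Integer seed or `NULL`.
#' @return A data frame.
#' @export
fiber_trajectories <- function(params, n_epochs = 1L, seed = NULL) {
  fibers <- init_fibers(params, seed)
  out <- vector("list", n_epochs * params$iters_per_epoch)
  k <- 0L
  for (e in seq_len(n_epochs)) {
    if (e > 1L) fibers <- branch_epoch(fibers)
    for (i in seq_len(params$iters_per_epoch) - 1L) {
      pts <- active_points(fibers, i)
      k <- k + 1L
      out[[k]] <- data.frame(epoch = e, iteration = i,
                             fiber = pts[, "fiber"], x = pts[, "x"],
                             y = pts[, "y"])
    }
  }
  do.call(rbind, out)
}
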