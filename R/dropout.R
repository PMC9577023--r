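# Dropout engine: convert fiber points into per-iteration masks, apply masks
# inside a training pass, simulate long-run drop statistics, and calibrate
# the fiber count n to a target average drop rate.

new_dropout_mask <- function(dropped, iteration = NA_integer_) {
  structure(
    list(iteration = iteration, dropped = dropped,
         realized_rate = mean(dropped)),
    class = "dropout_mask"
  )
}

#' @export
print.dropout_mask <- function(x, ...) {
  cat(sprintf("Dropout mask: %d/%d neurons dropped (rate %.3f)\n",
              sum(x$dropped), length(x$dropped), x$realized_rate))
  invisible(x)
}

#' Build a dropout mask from fiber points
#'
#' A neuron is dropped iff at least one active fiber point lies inside its
#' square. Multiple fibers hitting the same neuron have no extra effect
#' (fibers do not interact).
#'
#' @param grid A [neuron_grid()].
#' @param points Wrapped fiber points: n x 2 matrix in `[0, 1)^2` (an
#'   [active_points()] result may be passed directly; its `x`/`y` columns
#'   are used). May be empty.
#' @param iteration Optional iteration label stored on the mask.
#' @return A `dropout_mask`: logical `dropped` vector of length
#'   `grid$n_neurons` and its `realized_rate` (fraction dropped).
#' @export
mask_from_points <- function(grid, points, iteration = NA_integer_) {
  stopifnot(inherits(grid, "neuron_grid"))
  dropped <- logical(grid$n_neurons)
  if (length(points)) {
    if (is.matrix(points) && all(c("x", "y") %in% colnames(points)))
      points <- points[, c("x", "y"), drop = FALSE]
    pts <- as_points(points)
    idx <- point_to_neuron(grid, pts)
    idx <- idx[!is.na(idx)]
    dropped[idx] <- TRUE
  }
  new_dropout_mask(dropped, iteration)
}

#' Standard Bernoulli dropout mask
#'
#' Each neuron is dropped independently with probability `rate` — the
#' classical dropout baseline, with no spatial structure.
#'
#' @param n_neurons Number of neurons.
#' @param rate Drop probability p in `[0, 1]`.
#' @param seed Optional integer seed.
#' @return A `dropout_mask`.
#' @export
standard_dropout_mask <- function(n_neurons, rate, seed = NULL) {
  if (!is.numeric(rate) || length(rate) != 1L || is.na(rate) ||
      rate < 0 || rate > 1)
    stop_field("rate", "must be a single probability in [0, 1]")
  dropped <- with_seed(seed, stats::runif(n_neurons) < rate)
  new_dropout_mask(dropped)
}

#' Apply a dropout mask to activations
#'
#' In training mode, masked units are multiplied by zero, so they neither
#' contribute to the forward pass nor receive gradient through the product.
#' In evaluation mode activations pass through unchanged. By default no
#' inverted-dropout rescaling is applied (plain zeroing, symmetric across
#' FBM and Bernoulli modes); set `rescale_rate` to divide kept activations
#' by `1 - rescale_rate`.
#'
#' @param activations Numeric vector, or matrix with one row per unit.
#' @param mask A `dropout_mask` with as many entries as units.
#' @param training Logical; masks act only in training mode.
#' @param rescale_rate `NULL` (default, no rescaling) or the preset drop
#'   rate p used for inverted scaling 1/(1 - p).
#' @return Activations with dropped units zeroed.
#' @export
apply_mask <- function(activations, mask, training = TRUE,
                       rescale_rate = NULL) {
  stopifnot(inherits(mask, "dropout_mask"))
  n_units <- if (is.matrix(activations)) nrow(activations)
             else length(activations)
  if (n_units != length(mask$dropped))
    stop_field("activations",
               sprintf("has %d units but mask has %d", n_units,
                       length(mask$dropped)))
  if (!isTRUE(training)) return(activations)
  keep <- as.numeric(!mask$dropped)
  if (!is.null(rescale_rate)) {
    if (rescale_rate >= 1) stop_field("rescale_rate", "must be < 1")
    keep <- keep / (1 - rescale_rate)
  }
  if (is.matrix(activations)) activations * keep else activations * keep
}

#' Simulate the dropout process over a training schedule
#'
#' Runs a fiber population over `n_epochs` epochs of
#' `params$iters_per_epoch` iterations each (branching between epochs),
#' building the dropout mask at every iteration.
#'
#' @param grid A [neuron_grid()].
#' @param params A [fiber_params()].
#' @param n_epochs Number of epochs to simulate.
#' @param seed Integer seed or `NULL`.
#' @param keep_masks Logical; also return the full iteration x neuron
#'   logical mask matrix (memory: iterations * n_neurons).
#' @return An object of class `drop_rate_sim`: `rates` (realized drop
#'   fraction per iteration), `neuron_drops` (per-neuron drop counts over
#'   the whole schedule), `n_iterations`, and `masks` if requested.
#' @export
simulate_drop_rates <- function(grid, params, n_epochs, seed = NULL,
                                keep_masks = FALSE) {
  stopifnot(inherits(grid, "neuron_grid"), inherits(params, "fiber_params"))
  if (n_epochs < 1) stop_field("n_epochs", "must be >= 1")
  fibers <- init_fibers(params, seed)
  n_epochs <- as.integer(n_epochs)
  n_iter <- n_epochs * params$iters_per_epoch
  rates <- numeric(n_iter)
  drops <- integer(grid$n_neurons)
  masks <- if (keep_masks) matrix(FALSE, n_iter, grid$n_neurons) else NULL
  k <- 0L
  for (e in seq_len(n_epochs)) {
    if (e > 1L) fibers <- branch_epoch(fibers)
    for (i in seq_len(params$iters_per_epoch) - 1L) {
      m <- mask_from_points(grid, active_points(fibers, i), iteration = k)
      k <- k + 1L
      rates[k] <- m$realized_rate
      drops <- drops + m$dropped
      if (keep_masks) masks[k, ] <- m$dropped
    }
  }
  structure(
    list(rates = rates, neuron_drops = drops, n_iterations = n_iter,
         masks = masks, grid = grid, params = params, seed = seed),
    class = "drop_rate_sim"
  )
}

#' @export
print.drop_rate_sim <- function(x, ...) {
  cat(sprintf(
    "Dropout simulation: %d iterations, mean realized rate %.3f (sd %.3f)\n",
    x$n_iterations, mean(x$rates), stats::sd(x$rates)))
  invisible(x)
}

# Edge-adjacent (rook) neuron index pairs of a grid, as a 2-column matrix.
adjacent_pairs <- function(grid) {
  n <- grid$n_side
  idx <- function(row, col) row * n + col + 1L
  k <- 0:(n - 1L)
  horiz <- cbind(idx(rep(k, each = n - 1L), rep(0:(n - 2L), times = n)),
                 idx(rep(k, each = n - 1L), rep(1:(n - 1L), times = n)))
  vert <- cbind(idx(rep(0:(n - 2L), times = n), rep(k, each = n - 1L)),
                idx(rep(1:(n - 1L), times = n), rep(k, each = n - 1L)))
  rbind(horiz, vert)
}

#' Nearest-neighbor drop association of a mask sequence
#'
#' Measures the spatial structure of dropout: averaged over all
#' edge-adjacent neuron pairs, the difference between the joint drop
#' frequency and the product of marginal drop frequencies. Positive values
#' mean neighbors tend to be dropped together (the fiber mechanism's
#' signature); independent Bernoulli dropout gives zero in expectation.
#'
#' @param masks Logical iteration x neuron matrix (e.g. from
#'   [simulate_drop_rates()] with `keep_masks = TRUE`).
#' @param grid The [neuron_grid()] the masks were built on.
#' @return A list: `association` (mean joint minus product-of-marginals over
#'   adjacent pairs), `se` (standard error from the iteration-level spread
#'   of the joint term), and `n_pairs`.
#' @export
drop_association <- function(masks, grid) {
  stopifnot(is.matrix(masks), inherits(grid, "neuron_grid"),
            ncol(masks) == grid$n_neurons)
  pairs <- adjacent_pairs(grid)
  m <- masks * 1
  joint_t <- rowMeans(m[, pairs[, 1], drop = FALSE] *
                        m[, pairs[, 2], drop = FALSE])
  marg <- colMeans(m)
  indep <- mean(marg[pairs[, 1]] * marg[pairs[, 2]])
  list(association = mean(joint_t) - indep,
       se = stats::sd(joint_t) / sqrt(nrow(masks)),
       n_pairs = nrow(pairs))
}

#' Calibrate the fiber count to a target average drop rate
#'
#' The mean realized drop rate is non-decreasing in the number of fibers n;
#' this searches n by Monte-Carlo simulation (doubling bracket then binary
#' search, common random numbers per candidate) and returns the n whose
#' simulated mean rate is closest to `target_rate`.
#'
#' @param grid A [neuron_grid()].
#' @param params A [fiber_params()]; its `n_fibers` is ignored and replaced
#'   by each candidate.
#' @param target_rate Target mean drop rate in (0, 1).
#' @param seed Integer seed for the simulations.
#' @param n_iterations Minimum simulated iterations per candidate
#'   (default 500).
#' @param n_max Largest fiber count considered (default `4 * n_neurons`).
#' @return The calibrated fiber count (integer) with attribute
#'   `achieved_rate`.
#' @export
calibrate_fiber_count <- function(grid, params, target_rate, seed = NULL,
                                  n_iterations = 500L, n_max = NULL) {
  stopifnot(inherits(grid, "neuron_grid"), inherits(params, "fiber_params"))
  if (!is.numeric(target_rate) || length(target_rate) != 1L ||
      is.na(target_rate) || target_rate <= 0 || target_rate >= 1)
    stop_field("target_rate",
               "must lie strictly in (0, 1); use mode 'none' for 0")
  if (is.null(n_max)) n_max <- 4L * grid$n_neurons
  n_epochs <- ceiling(n_iterations / params$iters_per_epoch)
  mean_rate <- function(n) {
    p <- fiber_params(n_fibers = n, iters_per_epoch = params$iters_per_epoch,
                      window_len = params$window_len, shift = params$shift,
                      hurst = params$fbm$hurst, sigma = params$fbm$sigma,
                      dt = params$fbm$dt)
    mean(simulate_drop_rates(grid, p, n_epochs,
                             seed = derive_seed(seed, "cal", n))$rates)
  }
  # doubling bracket
  lo <- 1L; r_lo <- mean_rate(lo)
  if (r_lo >= target_rate) {
    res <- lo; attr(res, "achieved_rate") <- r_lo; return(res)
  }
  hi <- 2L
  r_hi <- mean_rate(hi)
  while (r_hi < target_rate && hi < n_max) {
    lo <- hi; r_lo <- r_hi
    hi <- min(2L * hi, n_max)
    r_hi <- mean_rate(hi)
  }
  if (r_hi < target_rate)
    stop(sprintf(
      "target_rate %.3f unattainable: achievable mean rate at n = %d is %.3f",
      target_rate, hi, r_hi), call. = FALSE)
  # binary search on the bracket [lo, hi]
  while (hi - lo > 1L) {
    mid <- lo + (hi - lo) %/% 2L
    r_mid <- mean_rate(mid)
    if (r_mid < target_rate) { lo <- mid; r_lo <- r_mid }
    else { hi <- mid; r_hi <- r_mid }
  }
  if (abs(r_lo - target_rate) <= abs(r_hi - target_rate)) {
    res <- lo; attr(res, "achieved_rate") <- r_lo
  } else {
    res <- hi; attr(res, "achieved_rate") <- r_hi
  }
  res
}
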