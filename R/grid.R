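# Euclidean embedding of a network layer: an N x N grid of square neurons in
# the unit square. Per axis, cell k occupies [k/N, k/N + 1/(2N)): cell then
# gap, each of width 1/(2N), tiling [0, 1] exactly. Covered area is 1/4 of
# the layer for every N. Under the periodic wrap the phase of the tiling is
# statistically irrelevant.

#' Construct an N x N neuron grid
#'
#' Neurons are squares of side `1/(2N)` spaced by `1/(2N)` in both
#' dimensions, laid out in the unit square. Flat neuron indices are 1-based
#' and row-major with row 0 at the bottom: `index = row * N + col + 1`, with
#' `col` from the x axis and `row` from the y axis.
#'
#' @param n_side Grid side N (positive integer); the layer has N^2 neurons.
#' @return An object of class `neuron_grid` with fields `n_side`,
#'   `cell_side`, `cell_spacing`, `n_neurons`, and `origins` (N^2 x 2 matrix
#'   of lower-left cell corners in flat-index order).
#' @examples
#' g <- neuron_grid(10)
#' g$n_neurons          # 100
#' g$cell_side          # 0.05
#' @export
neuron_grid <- function(n_side) {
  if (!is.numeric(n_side) || length(n_side) != 1L || is.na(n_side) ||
      n_side < 1 || n_side != round(n_side))
    stop_field("n_side", "must be a single positive integer")
  n <- as.integer(n_side)
  side <- 1 / (2 * n)
  k <- 0:(n - 1L)
  row <- rep(k, each = n)
  col <- rep(k, times = n)
  structure(
    list(n_side = n, cell_side = side, cell_spacing = side,
         n_neurons = n * n, rows = row, cols = col,
         origins = cbind(x0 = col / n, y0 = row / n)),
    class = "neuron_grid"
  )
}

#' @export
print.neuron_grid <- function(x, ...) {
  cat(sprintf(
    "%d x %d neuron grid: %d neurons, cell side = spacing = 1/%d\n",
    x$n_side, x$n_side, x$n_neurons, 2L * x$n_side))
  invisible(x)
}

#' Grid layout as a data frame
#'
#' One row per neuron: flat index, grid row/col, lower-left corner, side.
#' Suitable for CSV export and plotting.
#'
#' @param x A `neuron_grid`.
#' @param ... Unused.
#' @export
as.data.frame.neuron_grid <- function(x, ...) {
  data.frame(index = seq_len(x$n_neurons), row = x$rows, col = x$cols,
             x0 = x$origins[, 1], y0 = x$origins[, 2], side = x$cell_side)
}

#' Wrap points periodically into the unit square
#'
#' Reduces each coordinate modulo 1 into `[0, 1)`. This implements the
#' periodic boundary conditions: a fiber crossing a border re-enters on the
#' opposite side and never leaves the layer. Idempotent.
#'
#' @param points A length-2 point or an n x 2 matrix.
#' @return Wrapped coordinates, same shape as a matrix (n x 2).
#' @examples
#' wrap_periodic(c(1.25, -0.3))  # (0.25, 0.7)
#' @export
wrap_periodic <- function(points) {
  pts <- as_points(points)
  if (any(!is.finite(pts)))
    stop_field("points", "coordinates must be finite")
  pts %% 1
}

#' Map points to the neurons containing them
#'
#' Membership uses half-open cells `[x0, x0 + side) x [y0, y0 + side)`, so
#' no point belongs to two cells. Points falling in inter-neuron gaps map to
#' `NA`. Points must already be wrapped into `[0, 1)^2` (see
#' [wrap_periodic()]).
#'
#' @param grid A [neuron_grid()].
#' @param points A length-2 point or n x 2 matrix in `[0, 1)^2`.
#' @return Integer vector of 1-based flat neuron indices, `NA` for gaps.
#' @export
point_to_neuron <- function(grid, points) {
  stopifnot(inherits(grid, "neuron_grid"))
  pts <- as_points(points)
  if (any(!is.finite(pts)) || any(pts < 0) || any(pts >= 1))
    stop_field("points", "must lie in [0,1)^2; wrap with wrap_periodic() first")
  n <- grid$n_side
  ux <- pts[, 1] * n
  uy <- pts[, 2] * n
  cx <- floor(ux)
  cy <- floor(uy)
  inside <- (ux - cx) < 0.5 & (uy - cy) < 0.5
  idx <- as.integer(cy * n + cx + 1)
  idx[!inside] <- NA_integer_
  idx
}
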