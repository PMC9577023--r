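# Fractional Brownian motion: parameters, exact sample-path generation in one
# and two dimensions, and the closed-form second-order statistics used as
# test oracles.
#
# FBM B_H(t) is the zero-mean Gaussian process with
#   Cov(B(s), B(t)) = (sigma^2 / 2) (s^{2H} + t^{2H} - |s - t|^{2H}),
# so Var(B(t)) = sigma^2 t^{2H}.  H < 0.5 gives anti-persistent increments
# (subdiffusion), H = 0.5 ordinary Brownian motion, H > 0.5 persistent
# increments (superdiffusion).

#' FBM process parameters
#'
#' Bundle and validate the parameters of a discretely sampled fractional
#' Brownian motion: Hurst index `hurst` (H), scale `sigma`, time horizon
#' `t_max` (T) and time step `dt`. The discrete path has
#' `round(t_max / dt)` increments plus the starting point.
#'
#' @param hurst Hurst index H, in (0, 1). H = 0.5 is ordinary Brownian
#'   motion; H > 0.5 superdiffusion (persistent); H < 0.5 subdiffusion.
#' @param sigma Scale parameter, > 0. `Var(B(t)) = sigma^2 * t^(2*hurst)`.
#' @param t_max Process time horizon T, >= `dt`.
#' @param dt Time step, > 0.
#' @param seed Optional integer seed for reproducible generation.
#' @return An object of class `fbm_params`.
#' @examples
#' p <- fbm_params(hurst = 0.9, sigma = 1, t_max = 5, dt = 1 / 500)
#' p$n_steps
#' @export
fbm_params <- function(hurst, sigma = 1, t_max = 1, dt = 0.001, seed = NULL) {
  if (!is.numeric(hurst) || length(hurst) != 1L || is.na(hurst) ||
      hurst <= 0 || hurst >= 1)
    stop_field("hurst", "must be a single number strictly between 0 and 1")
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop_field("sigma", "must be a single positive number")
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop_field("dt", "must be a single positive number")
  if (!is.numeric(t_max) || length(t_max) != 1L || is.na(t_max) || t_max < dt)
    stop_field("t_max", "must be a single number >= dt")
  n_steps <- as.integer(round(t_max / dt))
  if (n_steps < 1L)
    stop_field("t_max", "round(t_max/dt) must be a positive number of steps")
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
      stop_field("seed", "must be a single integer or NULL")
    seed <- as.integer(seed)
  }
  structure(
    list(hurst = hurst, sigma = sigma, t_max = t_max, dt = dt,
         n_steps = n_steps, seed = seed),
    class = "fbm_params"
  )
}

#' @export
print.fbm_params <- function(x, ...) {
  cat(sprintf(
    "FBM parameters: H = %g, sigma = %g, T = %g, dt = %g (%d steps)\n",
    x$hurst, x$sigma, x$t_max, x$dt, x$n_steps))
  invisible(x)
}

#' Closed-form FBM covariance
#'
#' `Cov(B(t1), B(t2)) = (sigma^2/2) (t1^(2H) + t2^(2H) - |t1 - t2|^(2H))`.
#' Vectorized over `t1`/`t2`. Serves as the exact oracle the sample-path
#' generators are tested against.
#'
#' @param t1,t2 Non-negative times (recycled to a common length).
#' @param params An [fbm_params()] object.
#' @return Covariance value(s).
#' @examples
#' p <- fbm_params(0.5)
#' fbm_covariance(2, 5, p)  # = min(2, 5) for H = 0.5, sigma = 1
#' @export
fbm_covariance <- function(t1, t2, params) {
  stopifnot(inherits(params, "fbm_params"))
  if (any(t1 < 0) || any(t2 < 0))
    stop_field("t1/t2", "times must be non-negative")
  h2 <- 2 * params$hurst
  (params$sigma^2 / 2) * (t1^h2 + t2^h2 - abs(t1 - t2)^h2)
}

#' Correlation of consecutive FBM increments
#'
#' For two consecutive time intervals of equal length, the increment
#' correlation is `2^(2H - 1) - 1`: zero at H = 0.5 (independent
#' increments), positive for H > 0.5 (persistence), negative for H < 0.5
#' (anti-persistence).
#'
#' @param hurst Hurst index in (0, 1); vectorized.
#' @return Correlation value(s) in (-1/2, 1).
#' @export
fbm_increment_correlation <- function(hurst) {
  if (any(!is.finite(hurst)) || any(hurst <= 0) || any(hurst >= 1))
    stop_field("hurst", "must lie strictly between 0 and 1")
  2^(2 * hurst - 1) - 1
}

# Autocovariance gamma(0..kmax) of unit-variance fractional Gaussian noise
fgn_acov <- function(kmax, hurst) {
  k <- 0:kmax
  h2 <- 2 * hurst
  0.5 * ((k + 1)^h2 - 2 * k^h2 + abs(k - 1)^h2)
}

# Davies-Harte circulant embedding: exact fGn sample of length n, unit
# increment variance. Returns NULL when the embedding has a materially
# negative eigenvalue (caller falls back to Hosking).
fgn_davies_harte <- function(n, hurst) {
  g <- fgn_acov(n, hurst)                    # gamma(0..n)
  row <- if (n > 1) c(g, g[n:2]) else g      # circulant first row, length 2n
  lam <- Re(stats::fft(row))
  tol <- -1e-8 * max(lam)
  if (any(lam < tol)) return(NULL)
  lam[lam < 0] <- 0
  m <- 2L * n
  w <- complex(length.out = m)
  w[1L] <- sqrt(lam[1L] / m) * stats::rnorm(1L)
  if (n > 1L) {
    v1 <- stats::rnorm(n - 1L)
    v2 <- stats::rnorm(n - 1L)
    w[2:n] <- sqrt(lam[2:n] / (2 * m)) * complex(real = v1, imaginary = v2)
  }
  w[n + 1L] <- sqrt(lam[n + 1L] / m) * stats::rnorm(1L)
  if (n > 1L) w[(n + 2L):m] <- Conj(w[n:2])
  Re(stats::fft(w))[seq_len(n)]
}

# Hosking (Levinson-Durbin) recursion: exact fGn sample of length n. O(n^2);
# used only when the circulant embedding is not nonnegative definite.
fgn_hosking <- function(n, hurst) {
  g <- fgn_acov(n, hurst)                    # gamma(0..n), gamma(0) = 1
  x <- numeric(n)
  x[1L] <- stats::rnorm(1L)
  if (n == 1L) return(x)
  phi <- g[2L] / g[1L]
  v <- g[1L] * (1 - phi^2)
  x[2L] <- phi * x[1L] + sqrt(v) * stats::rnorm(1L)
  if (n >= 3L) {
    for (i in 2:(n - 1L)) {
      a <- (g[i + 1L] - sum(phi * g[i:2])) / v
      phi <- c(phi - a * rev(phi), a)
      v <- v * (1 - a^2)
      x[i + 1L] <- sum(phi * x[i:1]) + sqrt(v) * stats::rnorm(1L)
    }
  }
  x
}

# Draw one unit-variance fGn vector of length n (consuming the ambient RNG).
fgn_sample <- function(n, hurst) {
  z <- fgn_davies_harte(n, hurst)
  if (is.null(z)) z <- fgn_hosking(n, hurst)
  z
}

new_fbm_path <- function(values, params) {
  values <- as.matrix(values)
  structure(
    list(times = seq(0, by = params$dt, length.out = nrow(values)),
         values = values, params = params, dims = ncol(values)),
    class = "fbm_path"
  )
}

#' Generate a one-dimensional FBM sample path
#'
#' Exact Gaussian generation: fractional Gaussian noise by Davies-Harte
#' circulant embedding (Hosking recursion as fallback when the embedding is
#' not nonnegative definite), scaled by `sigma * dt^H` and cumulated. The
#' path starts at 0 and has `params$n_steps + 1` points.
#'
#' @param params An [fbm_params()] object.
#' @param seed Integer seed; defaults to `params$seed`. `NULL` draws from the
#'   ambient RNG.
#' @return An `fbm_path` object with elements `times`, `values` (one-column
#'   matrix), `params`, `dims`.
#' @examples
#' path <- fbm_1d(fbm_params(hurst = 0.9, t_max = 1, dt = 0.01, seed = 1))
#' head(as.data.frame(path))
#' @export
fbm_1d <- function(params, seed = params$seed) {
  stopifnot(inherits(params, "fbm_params"))
  incr <- with_seed(seed, fgn_sample(params$n_steps, params$hurst))
  incr <- incr * params$sigma * params$dt^params$hurst
  new_fbm_path(cbind(x = c(0, cumsum(incr))), params)
}

#' Generate a two-dimensional FBM sample path
#'
#' The two coordinates are independent one-dimensional FBM paths with the
#' same parameters, translated to start at `origin`.
#'
#' @param params An [fbm_params()] object.
#' @param origin Numeric length-2 starting point.
#' @param seed Integer seed; defaults to `params$seed`.
#' @return An `fbm_path` object whose `values` matrix has columns `x`, `y`
#'   and first row equal to `origin`.
#' @export
fbm_2d <- function(params, origin = c(0, 0), seed = params$seed) {
  stopifnot(inherits(params, "fbm_params"))
  if (!is.numeric(origin) || length(origin) != 2L || any(!is.finite(origin)))
    stop_field("origin", "must be a finite numeric vector of length 2")
  n <- params$n_steps
  sc <- params$sigma * params$dt^params$hurst
  inc <- with_seed(seed, {
    cbind(fgn_sample(n, params$hurst), fgn_sample(n, params$hurst))
  })
  vals <- cbind(x = origin[1] + c(0, cumsum(inc[, 1] * sc)),
                y = origin[2] + c(0, cumsum(inc[, 2] * sc)))
  new_fbm_path(vals, params)
}

#' @export
print.fbm_path <- function(x, ...) {
  cat(sprintf("%d-D FBM path: %d points, H = %g, sigma = %g, dt = %g\n",
              x$dims, nrow(x$values), x$params$hurst, x$params$sigma,
              x$params$dt))
  invisible(x)
}

#' @export
as.data.frame.fbm_path <- function(x, ...) {
  df <- data.frame(t = x$times)
  df$x <- x$values[, 1]
  if (x$dims >= 2L) df$y <- x$values[, 2]
  df
}

#' @export
plot.fbm_path <- function(x, ...) {
  if (x$dims == 1L) {
    graphics::plot(x$times, x$values[, 1], type = "l",
                   xlab = "t", ylab = "B(t)", ...)
  } else {
    graphics::plot(x$values[, 1], x$values[, 2], type = "l",
                   xlab = "x", ylab = "y", asp = 1, ...)
    graphics::points(x$values[1, 1], x$values[1, 2], pch = 16)
  }
  invisible(x)
}

#' Write a path to CSV
#'
#' Columns `t, x[, y]` for plotting or external inspection.
#'
#' @param path An `fbm_path`.
#' @param file Output file path.
#' @export
write_path_csv <- function(path, file) {
  stopifnot(inherits(path, "fbm_path"))
  utils::write.csv(as.data.frame(path), file, row.names = FALSE)
  invisible(file)
}
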