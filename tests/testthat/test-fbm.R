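# Fractional Brownian motion: parameter contracts, closed-form statistics,
# and exactness of the sample-path generators.

test_that("parameter validation names the offending field", {
  expect_error(fbm_params(hurst = 1.2), "hurst")
  expect_error(fbm_params(hurst = 0), "hurst")
  expect_error(fbm_params(0.5, sigma = -1), "sigma")
  expect_error(fbm_params(0.5, dt = 0), "dt")
  expect_error(fbm_params(0.5, t_max = 0.001, dt = 0.01), "t_max")
  expect_error(fbm_params(0.5, seed = "a"), "seed")
})

test_that("covariance matches its closed form", {
  p9 <- fbm_params(0.9, sigma = 2)
  # variance on the diagonal: sigma^2 t^{2H}
  for (t in c(0.5, 1, 10))
    expect_equal(fbm_covariance(t, t, p9), 4 * t^1.8)
  # H = 0.5 reduces to Brownian motion: Cov = sigma^2 min(s, t)
  p5 <- fbm_params(0.5)
  expect_equal(fbm_covariance(2, 5, p5), 2)
  expect_equal(fbm_covariance(7, 3, p5), 3)
  # the process is pinned at the origin
  expect_equal(fbm_covariance(0, 4.2, p9), 0)
  expect_error(fbm_covariance(-1, 2, p9), "negative|non-negative")
})

test_that("increment correlation follows 2^(2H-1) - 1", {
  expect_equal(fbm_increment_correlation(0.5), 0)
  expect_equal(fbm_increment_correlation(0.9), 2^0.8 - 1)
  expect_equal(fbm_increment_correlation(0.1), 2^(-0.8) - 1)
  # anti-persistent below 0.5, persistent above
  expect_lt(fbm_increment_correlation(0.25), 0)
  expect_gt(fbm_increment_correlation(0.75), 0)
  expect_error(fbm_increment_correlation(0), "hurst")
  expect_error(fbm_increment_correlation(1), "hurst")
})

test_that("paths start at the origin with the requested discretization", {
  p <- fbm_params(0.7, t_max = 2, dt = 0.05, seed = 4)
  path <- fbm_1d(p)
  expect_equal(nrow(path$values), p$n_steps + 1)
  expect_identical(unname(path$values[1, 1]), 0)
  expect_equal(path$times, seq(0, 2, by = 0.05))

  p2 <- fbm_2d(p, origin = c(0.3, 0.7))
  expect_equal(unname(p2$values[1, ]), c(0.3, 0.7))
  # coordinate streams are distinct independent draws
  expect_false(isTRUE(all.equal(p2$values[, 1] - 0.3,
                                p2$values[, 2] - 0.7)))
})

test_that("generation is bit-reproducible under a seed", {
  p <- fbm_params(0.9, t_max = 1, dt = 0.01)
  expect_identical(fbm_1d(p, seed = 11)$values, fbm_1d(p, seed = 11)$values)
  expect_false(identical(fbm_1d(p, seed = 11)$values,
                         fbm_1d(p, seed = 12)$values))
  expect_identical(fbm_2d(p, c(0.1, 0.2), seed = 5)$values,
                   fbm_2d(p, c(0.1, 0.2), seed = 5)$values)
})

test_that("generator covariance agrees with the Cholesky oracle and closed form", {
  n_paths <- 4000
  for (H in c(0.3, 0.9)) {
    p <- fbm_params(H, t_max = 16, dt = 1)
    tt <- seq_len(p$n_steps)
    theo <- outer(tt, tt, function(a, b) fbm_covariance(a, b, p))
    set.seed(21)
    emp_dh <- crossprod(sample_fbm_matrix(n_paths, p)) / n_paths
    set.seed(22)
    emp_ch <- crossprod(chol_fbm_paths(n_paths, p)) / n_paths
    z_dh <- cov_zscores(emp_dh, theo, n_paths)
    z_ch <- cov_zscores(emp_ch, theo, n_paths)
    expect_lt(max(abs(z_dh)), 5)
    expect_lt(max(abs(z_ch)), 5)
    # the two routes agree with each other within combined Monte-Carlo noise
    expect_lt(max(abs(emp_dh - emp_ch) /
                    sqrt((outer(diag(theo), diag(theo)) + theo^2) *
                           (2 / n_paths))), 5)
  }
})

test_that("Hosking fallback is itself an exact generator", {
  n_paths <- 4000
  p <- fbm_params(0.8, t_max = 8, dt = 1)
  set.seed(31)
  X <- t(replicate(n_paths, cumsum(fbmdropout:::fgn_hosking(8, 0.8))))
  tt <- seq_len(8)
  theo <- outer(tt, tt, function(a, b) fbm_covariance(a, b, p))
  z <- cov_zscores(crossprod(X) / n_paths, theo, n_paths)
  expect_lt(max(abs(z)), 5)
})

test_that("2-D coordinates are uncorrelated", {
  p <- fbm_params(0.5, t_max = 1, dt = 0.1)
  set.seed(41)
  ends <- t(vapply(1:4000, function(i) {
    v <- fbm_2d(p, seed = NULL)$values
    v[nrow(v), ]
  }, numeric(2)))
  expect_lt(abs(stats::cor(ends[, 1], ends[, 2])), 3 / sqrt(4000))
})

test_that("endpoint spread is self-similar with exponent H", {
  H <- 0.7
  n_paths <- 3000
  set.seed(51)
  sds <- vapply(c(1, 4, 16), function(T) {
    p <- fbm_params(H, t_max = T, dt = T / 64)
    stats::sd(vapply(seq_len(n_paths),
                     function(i) fbm_1d(p, seed = NULL)$values[65, 1],
                     numeric(1)))
  }, numeric(1))
  slope <- stats::coef(stats::lm(log(sds) ~ log(c(1, 4, 16))))[[2]]
  expect_lt(abs(slope - H), 0.05)
})

test_that("paths export to CSV with t, x, y columns", {
  p <- fbm_params(0.6, t_max = 0.1, dt = 0.01, seed = 2)
  f <- withr::local_tempfile(fileext = ".csv")
  write_path_csv(fbm_2d(p), f)
  df <- read.csv(f)
  expect_named(df, c("t", "x", "y"))
  expect_equal(nrow(df), 11)
})
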