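# Internal helpers: reproducible seed substreams and scoped RNG use.

#' Derive a deterministic substream seed
#'
#' Hashes a master seed together with an arbitrary sequence of integer or
#' character keys into a new seed in [0, 2^31 - 2]. Used so that every source
#' of randomness in a run (per fiber, per epoch, per dimension, per layer)
#' draws from its own reproducible stream. `NULL` propagates: with no master
#' seed, components draw from the ambient RNG.
#'
#' @param seed Integer master seed, or `NULL`.
#' @param ... Integer or character keys identifying the substream.
#' @return An integer seed, or `NULL` if `seed` is `NULL`.
#' @keywords internal
derive_seed <- function(seed, ...) {
  if (is.null(seed)) return(NULL)
  keys <- list(...)
  h <- (abs(as.double(seed)) + 1) %% 2147483647
  for (k in keys) {
    kv <- if (is.character(k)) {
      u <- utf8ToInt(k)
      sum(u * seq_along(u))
    } else {
      abs(as.double(k))
    }
    # Lehmer-style mix; all intermediates stay below 2^53
    h <- (h * 48271 + kv + 11) %% 2147483647
  }
  as.integer(h)
}

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the prior
#' RNG state so scoped draws do not perturb the caller's stream. With
#' `seed = NULL` the code simply runs against the current RNG.
#'
#' @param seed Integer seed or `NULL`.
#' @param code Expression to evaluate (lazily).
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  code
}

# stop() with a message naming the offending argument/field
stop_field <- function(field, msg) {
  stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
}

# coerce a point or point set to an n x 2 matrix
as_points <- function(points) {
  if (is.null(dim(points))) {
    if (length(points) != 2L)
      stop_field("points", "a single point must have exactly 2 coordinates")
    points <- matrix(as.numeric(points), nrow = 1L)
  }
  pts <- as.matrix(points)
  if (ncol(pts) != 2L)
    stop_field("points", "points must be 2-D (two columns)")
  storage.mode(pts) <- "double"
  pts
}
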