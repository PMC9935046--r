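# Seeding utilities: every stochastic operation draws from an isolated RNG
# stream so that package functions never disturb the caller's .Random.seed,
# and a single global seed deterministically derives all stage seeds.

local_rng <- function(seed) {
  state <- NULL
  draw <- function(fn, ...) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(seed) else
      assign(".Random.seed", state, envir = globalenv())
    res <- fn(...)
    state <<- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv()) else
      rm(".Random.seed", envir = globalenv())
    res
  }
  list(
    runif = function(n, min = 0, max = 1) draw(stats::runif, n, min, max),
    rnorm = function(n, mean = 0, sd = 1) draw(stats::rnorm, n, mean, sd),
    sample = function(x, size, replace = FALSE) draw(sample, x, size, replace)
  )
}

#' Derive a stage seed from a global seed
#'
#' Deterministic splitting rule mapping (global seed, stage tag, index) to
#' a 32-bit-safe integer seed, so one global seed drives every stage of
#' the pipeline reproducibly.
#'
#' @param global_seed Integer.
#' @param tag Character stage tag.
#' @param index Integer sub-index within the stage.
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(global_seed, tag, index = 0L) {
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((as.numeric(global_seed) * 1000003 + h * 7919 + index * 104729) %%
               2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cross3 <- function(a, b) {
  # row-wise cross product of n x 3 matrices
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

clamp01 <- function(x) {
  # elementwise clamp to [0, 1], preserving matrix shape
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

wrap_angle <- function(x) {
  # wrap to (-pi, pi]
  m <- x %% (2 * pi)
  ifelse(m > pi, m - 2 * pi, m)
}
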