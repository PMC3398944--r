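`%||%` <- function(a, b) if (is.null(a)) b else a

## Internal RNG helpers: draw from a private stream identified by `seed`
## without disturbing the caller's global RNG state.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

.seeded_rng <- function(seed) {
  state <- NULL
  use <- function(fn, ...) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(seed)
    else assign(".Random.seed", state, envir = globalenv())
    out <- fn(...)
    state <<- get(".Random.seed", envir = globalenv())
    if (had) assign(".Random.seed", old, envir = globalenv())
    else rm(".Random.seed", envir = globalenv())
    out
  }
  list(
    rnorm = function(n, mean = 0, sd = 1) use(stats::rnorm, n, mean, sd),
    runif = function(n, min = 0, max = 1) use(stats::runif, n, min, max),
    sample_int = function(n, size, replace = FALSE)
      use(sample.int, n, size, replace)
  )
}
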