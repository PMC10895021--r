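# Internal helpers shared across the package.

# Rethrow any error from `expr` with the pipeline stage name prepended, so a
# failure deep in a multi-stage computation reports where it happened.
with_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE)
  })
}

# Run `expr` with the RNG seeded to `seed`, restoring the caller's RNG state
# afterwards so generators are pure functions of their arguments.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

rms <- function(x) sqrt(mean(x^2))

db <- function(ratio) 20 * log10(ratio)

`%||%` <- function(a, b) if (is.null(a)) b else a
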