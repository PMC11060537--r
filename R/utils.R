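# Self-contained RNG streams. Every stochastic function in the package draws
# from a stream created here, so nothing touches (or depends on) the caller's
# .Random.seed, and one master seed can be split reproducibly into
# per-participant / per-cohort child streams.

.new_rng <- function(seed) {
  seed <- as.integer(seed)
  if (is.na(seed)) stop("seed must be an integer", call. = FALSE)
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed, kind = "Mersenne-Twister")
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) rm(".Random.seed", envir = globalenv())
  else assign(".Random.seed", old, envir = globalenv())
  env
}

# evaluate expr with the stream's state installed, then put things back
.rng_eval <- function(rng, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", globalenv())
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

.rng_shuffle <- function(rng, n) .rng_eval(rng, sample.int(n))

# child seeds below 2^31, derived from the stream
.rng_child_seeds <- function(rng, n) {
  .rng_eval(rng, sample.int(.Machine$integer.max, n, replace = FALSE))
}

.assert_prob <- function(x, name) {
  if (!is.numeric(x) || any(x < 0) || any(x > 1))
    stop("'", name, "' must be a probability in [0, 1]", call. = FALSE)
}

.assert_pos <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x <= 0))
    stop("'", name, "' must be a positive number", call. = FALSE)
}
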