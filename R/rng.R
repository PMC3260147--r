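#' Independent seeded random-number streams
#'
#' Each stateful component (unit, actuator, environment) owns its own stream
#' so that identical seeds plus identical call sequences reproduce identical
#' draws regardless of what other components do. A stream is a snapshot of
#' R's Mersenne-Twister state that is swapped in around every draw.
#'
#' @param seed integer seed for the stream.
#' @return an object of class `ampf_rng` (an environment holding the state).
#' @export
rng_handle <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  h <- new.env(parent = emptyenv())
  old <- .save_global_seed()
  set.seed(as.integer(seed))
  h$state <- get(".Random.seed", envir = globalenv())
  .restore_global_seed(old)
  h$seed <- as.integer(seed)
  class(h) <- "ampf_rng"
  h
}

.save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_global_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Evaluate an expression using a stream's RNG state
#'
#' @param h an `ampf_rng` stream.
#' @param expr expression evaluated with the stream's state installed; the
#'   advanced state is written back to the stream afterwards.
#' @return the value of `expr`.
#' @export
with_rng <- function(h, expr) {
  old <- .save_global_seed()
  assign(".Random.seed", h$state, envir = globalenv())
  on.exit({
    h$state <- get(".Random.seed", envir = globalenv())
    .restore_global_seed(old)
  })
  expr
}

#' @rdname with_rng
#' @param n number of draws.
#' @param min,max uniform bounds.
#' @export
rng_runif <- function(h, n, min = 0, max = 1) with_rng(h, stats::runif(n, min, max))

#' @rdname with_rng
#' @param mean,sd normal moments.
#' @export
rng_rnorm <- function(h, n, mean = 0, sd = 1) with_rng(h, stats::rnorm(n, mean, sd))

#' @rdname with_rng
#' @param k upper bound; draws one integer uniformly from `1:k`.
#' @export
rng_int <- function(h, k) with_rng(h, sample.int(k, 1L))

# Serializable snapshot of a stream, and its inverse (for checkpoints).
rng_snapshot <- function(h) list(seed = h$seed, state = as.integer(h$state))
rng_restore <- function(snap) {
  h <- rng_handle(snap$seed)
  h$state <- as.integer(snap$state)
  h
}
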