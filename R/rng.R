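# Independent RNG substreams, one per stochastic process, so that toggling
# one mechanism leaves the draw sequences of the others untouched.
# Common-random-number comparisons (threshold monotonicity, directional
# parameter effects) rely on this isolation.

.getRandomSeed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.setRandomSeed <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

# Capture the generator state that set.seed(seed) would produce, without
# disturbing the caller's RNG state.
.seedState <- function(seed) {
  old <- .getRandomSeed()
  on.exit(.setRandomSeed(old))
  set.seed(as.integer(seed))
  get(".Random.seed", envir = globalenv())
}

#' Create named independent RNG substreams
#'
#' Each stream is an independently seeded Mersenne-Twister state derived
#' deterministically from a single master seed. Streams are stored in an
#' environment and advanced individually by [drawFromStream()].
#'
#' @param master integer master seed (kept below 2^31).
#' @param names character vector of stream names.
#' @return an environment mapping stream name to RNG state.
#' @export
makeRngStreams <- function(master, names) {
  stopifnot(is.numeric(master), length(master) == 1, length(names) >= 1)
  env <- new.env(parent = emptyenv())
  for (k in seq_along(names)) {
    seed <- (abs(as.numeric(master)) * 48271 + k * 2654435) %% 2147483629
    env[[names[k]]] <- .seedState(seed)
  }
  env
}

#' Evaluate a random draw inside a named substream
#'
#' Swaps the named stream state into the global generator, evaluates `fun()`,
#' saves the advanced state back and restores the caller's RNG state.
#'
#' @param streams environment from [makeRngStreams()].
#' @param name stream name.
#' @param fun zero-argument function performing the draws.
#' @return the value of `fun()`.
#' @export
drawFromStream <- function(streams, name, fun) {
  if (!exists(name, envir = streams, inherits = FALSE))
    stop("unknown RNG stream: ", name)
  old <- .getRandomSeed()
  .setRandomSeed(get(name, envir = streams))
  res <- fun()
  assign(name, get(".Random.seed", envir = globalenv()), envir = streams)
  .setRandomSeed(old)
  res
}

# Evaluate expr under a fixed seed, restoring the caller's RNG state after.
withSeed <- function(seed, expr) {
  old <- .getRandomSeed()
  on.exit(.setRandomSeed(old))
  set.seed(as.integer(seed))
  expr
}
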