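# Deterministic seeding.  Every stochastic component (sampler, weight init,
# augmentation, synthetic data) owns a private RNG stream derived from the
# run seed, so components never perturb each other's sequences and two runs
# with equal seed and config are bitwise-reproducible.

#' Create a private RNG stream
#'
#' A stream is an environment holding its own `.Random.seed` state; use
#' [with_rng()] to evaluate stochastic code under it.  Streams are
#' independent of the global RNG and of each other.
#'
#' @param seed non-negative integer seed.
#' @return an environment of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0)
  e <- new.env(parent = emptyenv())
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(as.integer(seed %% .Machine$integer.max))
  e$state <- get(".Random.seed", envir = globalenv())
  if (has_old) assign(".Random.seed", old, envir = globalenv())
  class(e) <- "rng_stream"
  e
}

#' Evaluate code under a private RNG stream
#'
#' Swaps the stream's state into `.Random.seed`, evaluates `code`, then
#' captures the advanced state back into the stream and restores the global
#' RNG exactly as it was.
#'
#' @param stream an [rng_stream()].
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_rng <- function(stream, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (has_old) assign(".Random.seed", old, envir = globalenv())
  })
  code
}

#' Derive a child seed for a named component
#'
#' Deterministic hash of (parent seed, component name), kept below 2^31 so
#' it is always a valid R integer seed.
#'
#' @param seed parent integer seed.
#' @param name component name, e.g. `"sampler"`.
#' @return integer child seed.
#' @export
child_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Build the standard set of component RNG streams for a run
#'
#' @param seed run seed (defaults to 42 when `NULL`).
#' @return named list of [rng_stream()]s: `split`, `sampler`, `init`,
#'   `augment`, `portion`, `synth`.
#' @export
seed_everything <- function(seed = NULL) {
  if (is.null(seed)) seed <- 42L
  comps <- c("split", "sampler", "init", "augment", "portion", "synth")
  streams <- lapply(comps, function(nm) rng_stream(child_seed(seed, nm)))
  names(streams) <- comps
  streams$seed <- as.integer(seed)
  streams
}
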