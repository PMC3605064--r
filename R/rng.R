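# Named RNG substreams: sprouting, growth-direction noise, adaptation
# noise and fixture generation draw from separate streams derived from one
# master seed, so toggling one mechanism off does not shift the draws seen
# by the others (clean knockout comparisons).

#' Create named random-number substreams
#'
#' @param seed master integer seed.
#' @param names stream names.
#' @return environment of class \code{rng_streams} holding one saved RNG
#'   state per name.
#' @export
rng_streams <- function(seed,
                        names = c("sprout", "direction", "ks", "fixture")) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  for (i in seq_along(names)) {
    set.seed((as.integer(seed) %% 599999L) * 3001L + i * 7919L)
    assign(names[i], get(".Random.seed", globalenv()), envir = env)
  }
  if (!is.null(old)) assign(".Random.seed", old, globalenv())
  class(env) <- "rng_streams"
  env
}

#' Evaluate an expression under a named substream
#'
#' Swaps in the saved state of the stream, evaluates, saves the advanced
#' state back, and restores the ambient RNG state.
#'
#' @param streams an \code{rng_streams}.
#' @param name stream name.
#' @param expr expression to evaluate.
#' @export
with_stream <- function(streams, name, expr) {
  if (!exists(name, envir = streams, inherits = FALSE)) {
    stop("no RNG stream named ", name)
  }
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  assign(".Random.seed", get(name, envir = streams), globalenv())
  on.exit({
    assign(name, get(".Random.seed", globalenv()), envir = streams)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  expr
}
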