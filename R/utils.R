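# Seeded RNG streams that leave the caller's .Random.seed untouched, so the
# generators are pure functions of (arguments, seed).

local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$state <- NULL
  swap_in <- function() {
    env$outer <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    if (is.null(env$state)) {
      set.seed(as.integer(seed))
    } else {
      assign(".Random.seed", env$state, globalenv())
    }
  }
  swap_out <- function() {
    env$state <- get(".Random.seed", globalenv())
    if (is.null(env$outer)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", env$outer, globalenv())
    }
  }
  wrap <- function(f) {
    function(...) {
      swap_in()
      on.exit(swap_out())
      f(...)
    }
  }
  list(runif = wrap(stats::runif),
       rnorm = wrap(stats::rnorm),
       sample = wrap(function(x, size, prob = NULL)
         sample(x, size, replace = FALSE, prob = prob)))
}
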