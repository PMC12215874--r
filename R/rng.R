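# Named RNG substreams.  Each stream owns a private .Random.seed so that the
# optimizer's independent randomness sources (init, movement, signs, mode
# draws, snake displacement) do not perturb one another: adding or removing
# draws in one stream never shifts another stream's sequence.

new_rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

# deterministic sub-seed derivation; stays within 32-bit integer range
derive_seed <- function(root, index) {
  ((abs(as.numeric(root)) %% 1e5) * 1009 + index * 7919 + 17) %% 2147483647
}

#' Create a set of independent named RNG substreams from one root seed
#' @noRd
new_rng_streams <- function(root_seed, names) {
  streams <- lapply(seq_along(names), function(i) new_rng_stream(derive_seed(root_seed, i)))
  names(streams) <- names
  streams
}

with_stream <- function(stream, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

stream_runif <- function(stream, n, min = 0, max = 1) {
  with_stream(stream, stats::runif(n, min, max))
}

stream_rnorm <- function(stream, n, mean = 0, sd = 1) {
  with_stream(stream, stats::rnorm(n, mean, sd))
}

stream_sample_int <- function(stream, n, size = 1L, replace = FALSE) {
  with_stream(stream, sample.int(n, size = size, replace = replace))
}

# +1 / -1 draws for the snake "diversity factor" +- operator
stream_signs <- function(stream, n, prob_plus = 0.5) {
  ifelse(stream_runif(stream, n) < prob_plus, 1, -1)
}
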