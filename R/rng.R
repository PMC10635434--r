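#' Derive a deterministic sub-stream seed
#'
#' Every generator in the package consumes randomness through a named
#' sub-stream derived from a single master seed, so adding a generator call
#' to a script never perturbs the draws of another. The sub-stream seed is a
#' polynomial hash of the stream name folded into the master seed, reduced
#' modulo 2^31 - 1 so it is always a valid 32-bit R integer.
#'
#' @param seed master integer seed.
#' @param stream character scalar naming the sub-stream.
#' @return an integer seed.
#' @export
#' @examples
#' substream_seed(1L, "depth")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream),
            length(stream) == 1L)
  m <- 2147483647
  h <- as.double(abs(seed)) %% m
  for (b in utf8ToInt(stream)) h <- (h * 31 + b) %% m
  as.integer(h)
}

#' Evaluate code under a sub-stream seed, restoring RNG state afterwards
#'
#' @param seed master integer seed.
#' @param stream sub-stream name, see [substream_seed()].
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_substream <- function(seed, stream, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(substream_seed(seed, stream))
  force(code)
}
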