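#' Derive a named substream seed from a master seed
#'
#' All randomness in the pipeline flows from one master seed. Each stage
#' draws from its own substream, derived deterministically from the master
#' seed and a stage name, so any stage can be regenerated independently of
#' the others (regenerating the BOLD series does not perturb the cohort).
#'
#' The derivation is a small multiplicative hash of the stage name folded
#' into the master seed modulo 2^31 - 19 (a prime below the 32-bit integer
#' ceiling), which keeps derived seeds valid R integers.
#'
#' @param master integer master seed.
#' @param stream character stage name, e.g. `"cohort"`, `"kmeans"`,
#'   `"world"`, `"bold"`.
#' @return A single integer seed.
#' @export
#' @examples
#' substream_seed(1L, "cohort")
substream_seed <- function(master, stream) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stream))
  m <- 2147483629  # 2^31 - 19, prime
  h <- 0
  for (code in utf8ToInt(stream)) h <- (h * 131 + code) %% m
  as.integer((abs(as.numeric(master)) %% m * 7919 + h) %% m)
}

# Run an expression under a local RNG state seeded from `seed`; the caller's
# RNG stream is restored afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
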