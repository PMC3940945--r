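# Seed handling: every stochastic operation takes an explicit seed and leaves
# the caller's RNG state untouched.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so package internals never perturb the
#' user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a per-slide seed from a master seed and an index
#'
#' Multiplicative mixing modulo the Mersenne prime 2^31 - 1, so any slide of a
#' cohort can be regenerated in isolation from the master seed alone. Both
#' factors stay below 2^53 so the arithmetic is exact in doubles.
#'
#' @param master_seed integer master seed.
#' @param index positive integer (slide index, or any stream discriminator).
#' @return An integer seed in [1, 2^31 - 2].
#' @export
derive_seed <- function(master_seed, index) {
  m <- 2147483647 # 2^31 - 1
  s <- (abs(as.numeric(master_seed)) %% m)
  h <- (s * 48271 + as.numeric(index) * 1299709 + 12345) %% m
  h <- (h * 69621) %% m
  as.integer(h + 1)
}
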