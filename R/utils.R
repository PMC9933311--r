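#' Round half away from zero toward the next integer (round-half-up)
#'
#' Single rounding convention used for every integerisation in the package
#' (grey-level conversion, projections, rendering). `round()` in R rounds
#' half to even, which would make results depend on parity.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector, `floor(x + 0.5)`.
#' @keywords internal
roundHalfUp <- function(x) floor(x + 0.5)

# clamp to the 8-bit range (dims preserved)
clamp8 <- function(x) {
  x[x < 0] <- 0
  x[x > 255] <- 255
  x
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards so library code never perturbs user RNG.
withSeed <- function(seed, expr) {
  env <- globalenv()
  has <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (has) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  expr
}

# stopifnot-style check with a formatted message
assertThat <- function(ok, ...) {
  if (!isTRUE(ok)) stop(sprintf(...), call. = FALSE)
  invisible(TRUE)
}
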