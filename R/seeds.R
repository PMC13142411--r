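# Seed plumbing. All randomness flows from one root seed split into named
# streams so that components (splitting, init, training, sampling) can be
# reproduced independently. withSeed() evaluates an expression under a
# temporary RNG state and restores the caller's state afterwards.

withSeed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  eval.parent(substitute(expr))
}

#' Derive a named sub-seed from a root seed
#'
#' Deterministic, platform-stable derivation of independent seeds for the
#' package's named random streams (`"split"`, `"init"`, `"training"`,
#' `"sampling"`, ...). Always returns a non-negative integer below 2^31.
#'
#' @param seed Root integer seed.
#' @param stream Stream name.
#' @return An integer seed.
#' @export
deriveSeed <- function(seed, stream) {
  bytes <- utf8ToInt(paste0(stream, ":", as.integer(seed)))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}
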