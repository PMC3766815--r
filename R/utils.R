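# Internal helpers shared across modules.

# Derive a stage seed from a master seed by stable hashing of the stage name.
# Keeps independent streams for pipeline stages while remaining a pure
# function of (master seed, stage label); result fits in a 32-bit integer.
deriveSeed <- function(masterSeed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) h <- (h * 31 + code) %% 2147483647
  as.integer((as.numeric(masterSeed) * 2654435 + h) %% 2147483647)
}

# run expr with a locally-set RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(),
                       inherits = FALSE))
      rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  expr
}

stopIfNot1 <- function(x, what) {
  if (length(x) != 1 || is.na(x)) stop(what, " must be a single value")
  x
}

checkProportion <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
    stop(name, " must be a proportion in [0, 1]")
  x
}

checkNonNeg <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x < 0)
    stop(name, " must be a single non-negative number")
  x
}

checkCount <- function(x, name, min = 1L) {
  if (length(x) != 1 || !is.finite(x) || x != round(x) || x < min)
    stop(name, " must be an integer >= ", min)
  as.integer(x)
}
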