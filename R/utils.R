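# Internal helpers: seed plumbing shared by the generator, the simulator
# and the permutation tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with the RNG seeded to `seed`, restoring the caller's RNG
# state afterwards so library code never clobbers the user's stream.
withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive n reproducible child seeds from one master seed. Children are
# drawn below 2^31 - 1 so they remain valid R integer seeds.
childSeeds <- function(seed, n) {
  withSeed(seed, sample.int(2147483646L, n))
}

assertCount <- function(x, name) {
  if (length(x) != 1L || is.na(x) || x < 1)
    stop(sprintf("'%s' must be a single count >= 1", name), call. = FALSE)
  as.integer(x)
}

upperTriValues <- function(m) m[upper.tri(m)]
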