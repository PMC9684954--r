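## Internal helpers.

## Evaluate `expr` under a temporary RNG seed, restoring the caller's RNG
## state afterwards so library code never perturbs user-level randomness.
.withSeed <- function(seed, expr) {
  has_state <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_state) old <- get(".Random.seed", envir = globalenv())
  set.seed(seed)
  on.exit({
    if (has_state) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  expr
}

## Derive a stream of child seeds from one master seed (kept below 2^31).
.childSeeds <- function(seed, n) {
  .withSeed(seed, sample.int(.Machine$integer.max - 1L, n))
}

.logistic <- function(x) 1 / (1 + exp(-x))

## Pearson correlation that tolerates zero-variance inputs (returns NA).
.safeCor <- function(x, y, method = "pearson") {
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y, method = method)
}
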