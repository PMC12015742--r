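#' Derive a child seed from a global seed
#'
#' One global seed expands to per-component seeds by fixed offsets, so that
#' regenerating one component never perturbs the random stream of another.
#' The map stays within the 32-bit positive-integer range `set.seed` accepts.
#'
#' @param seed global integer seed.
#' @param offset fixed non-negative integer offset identifying the component.
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
child_seed <- function(seed, offset) {
  s <- (as.numeric(seed) %% 2147483647) * 48271 + as.numeric(offset) * 65537 + 1
  as.integer(s %% 2147483646) + 1L
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
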