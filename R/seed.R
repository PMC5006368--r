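# Run an expression with a locally seeded RNG, restoring (or clearing)
# the caller's RNG state afterwards, so seeded operations never disturb
# the global random stream. seed = NULL uses the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded child seed from a parent seed and a stream index,
# keeping the result inside the 32-bit integer range.
child_seed <- function(seed, k) {
  (as.double(seed) * 48271 + 7919 * k) %% 2147483647
}
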